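# Spreadsheet-driven batch execution: parse the input sheet, determine
# the entry point per dataset, build an ordered queue of processing
# steps, run every job with per-job failure isolation, and emit results,
# logs and quality-check outputs.

.known_keywords <- c("convert", "noise", "noiseai", "phase", "phaseai",
                     "alias", "aliasai", "seg", "regions",
                     "pwv", "vmax", "ke", "el", "qc")

.canonical_order <- .known_keywords

.ai_keywords <- c("noiseai", "phaseai", "aliasai")

.quant_keywords <- c("pwv", "vmax", "ke", "el")

#' Register an AI processing plug-in
#'
#' The `noiseai`, `phaseai` and `aliasai` keywords dispatch to an
#' extension hook. No trained models ship with the package, so by default
#' these steps fail with "model not available"; a plug-in function
#' `function(ds, context) -> ds` may be registered here.
#'
#' @param keyword one of `"noiseai"`, `"phaseai"`, `"aliasai"`.
#' @param fun the plug-in function, or `NULL` to unregister.
#' @return Previous registration, invisibly.
#' @export
register_ai_module <- function(keyword, fun) {
  stopifnot(keyword %in% .ai_keywords)
  old <- .af_state[[keyword]]
  .af_state[[keyword]] <- fun
  invisible(old)
}

parse_params_fragment <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) af_stop("malformed params fragment: '", p, "'")
    out[[trimws(kv[1])]] <- utils::type.convert(trimws(kv[2]), as.is = TRUE)
  }
  out
}

#' Parse the batch input sheet
#'
#' Reads a CSV with a header row and columns `Subject ID`, `Data Path`,
#' `Steps` (semicolon-separated processing keywords) and optionally
#' `Params` (semicolon-separated `key=value` overrides). Rows with
#' unknown keywords, missing paths or duplicate subject ids yield a
#' failed run record without stopping the parse.
#'
#' @param path CSV file.
#' @return A list: `jobs` (list of `job_spec`) and `failures` (list of
#'   failed `run_record`s).
#' @export
parse_input_sheet <- function(path) {
  if (!file.exists(path)) af_stop("parse_input_sheet: cannot read ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 strip.white = TRUE)
  need <- c("Subject ID", "Data Path", "Steps")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    af_stop("parse_input_sheet: missing columns: ",
            paste(missing_cols, collapse = ", "))
  }
  jobs <- list()
  failures <- list()
  seen <- character(0)
  for (i in seq_len(nrow(df))) {
    id <- trimws(df[["Subject ID"]][i])
    dp <- trimws(df[["Data Path"]][i])
    steps_raw <- trimws(strsplit(df[["Steps"]][i], ";", fixed = TRUE)[[1]])
    steps_raw <- steps_raw[nzchar(steps_raw)]
    fail <- function(msg) {
      failures[[length(failures) + 1]] <<- run_record(id, "failed", error = msg)
    }
    if (!nzchar(id)) { fail("missing subject id"); next }
    if (id %in% seen) { fail(paste0("duplicate subject id: ", id)); next }
    unknown <- setdiff(steps_raw, .known_keywords)
    if (length(unknown)) {
      fail(paste0("unknown keyword: ", paste(unknown, collapse = ", ")))
      next
    }
    if (!nzchar(dp)) { fail("missing data path"); next }
    params <- tryCatch(parse_params_fragment(df[["Params"]][i] %||% NA),
                       error = function(e) e)
    if (inherits(params, "error")) { fail(conditionMessage(params)); next }
    seen <- c(seen, id)
    steps <- .canonical_order[.canonical_order %in% steps_raw]
    jobs[[length(jobs) + 1]] <- structure(
      list(subject_id = id, data_path = dp, steps = steps,
           params_override = params),
      class = "job_spec"
    )
  }
  list(jobs = jobs, failures = failures)
}

run_record <- function(subject_id, status, error = NULL, timings = NULL,
                       outputs = NULL) {
  structure(
    list(subject_id = subject_id, status = status, error_text = error,
         timings = timings, outputs = outputs),
    class = "run_record"
  )
}

# Entry-point detection: DICOM directory vs. HDF5 container, mask or not.
detect_entry <- function(data_path) {
  if (dir.exists(data_path)) return("dicom")
  if (file.exists(data_path) && grepl("\\.(h5|hdf5)$", data_path)) {
    return(if (h5_has_mask(data_path)) "h5_mask" else "h5")
  }
  af_stop("cannot determine entry point for '", data_path,
          "': not a DICOM directory or HDF5 container")
}

#' Build the ordered processing queue for a job
#'
#' Steps are re-ordered canonically (convert, noise, phase, alias,
#' segmentation, regions, quantifications, qc) regardless of sheet order.
#' The entry point is auto-detected from the data path (DICOM directory
#' vs. HDF5 container, segmentation present or absent); steps that do not
#' apply to the entry point (preprocessing/segmentation of an already
#' processed dataset with a mask) are skipped with a logged notice.
#' Quantifications requested without any segmentation available fail the
#' queue build.
#'
#' @param job a `job_spec` from [parse_input_sheet()].
#' @return A list: `entry`, `steps` (keywords to execute), `notices`.
#' @export
build_queue <- function(job) {
  entry <- detect_entry(job$data_path)
  steps <- job$steps
  notices <- character(0)
  if (entry == "dicom" && !("convert" %in% steps)) {
    steps <- c("convert", steps)
    notices <- c(notices, "DICOM entry: conversion queued implicitly")
  }
  if (entry != "dicom" && "convert" %in% steps) {
    steps <- setdiff(steps, "convert")
    notices <- c(notices, "convert skipped: input already in container format")
  }
  if (entry == "h5_mask") {
    drop <- intersect(steps, c("noise", "noiseai", "phase", "phaseai",
                               "alias", "aliasai", "seg"))
    if (length(drop)) {
      steps <- setdiff(steps, drop)
      notices <- c(notices,
                   paste0("already processed (mask present): skipping ",
                          paste(drop, collapse = ", ")))
    }
  }
  wants_quant <- any(.quant_keywords %in% steps)
  has_seg_source <- entry == "h5_mask" || "seg" %in% steps
  if (wants_quant && !has_seg_source) {
    af_stop("build_queue: segmentation required for ",
            paste(intersect(.quant_keywords, steps), collapse = ", "),
            " but no mask is present and no 'seg' step was requested")
  }
  if (any(c("vmax", "ke", "el") %in% steps) && !("regions" %in% steps)) {
    steps <- c(steps, "regions")
    notices <- c(notices, "regions queued implicitly for regional quantification")
  }
  steps <- .canonical_order[.canonical_order %in% steps]
  list(entry = entry, steps = steps, notices = notices)
}

# merge config defaults with per-job overrides
job_config <- function(config, overrides) {
  cfg <- config %||% list()
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  pp_args <- cfg[intersect(names(cfg), names(formals(preprocess_params)))]
  cfg$preprocess <- do.call(preprocess_params, pp_args)
  cfg$seg_fraction <- cfg$seg_fraction %||% 0.2
  cfg$plane_spacing <- cfg$plane_spacing %||% 25
  cfg$el_boundary <- cfg$el_boundary %||% "include"
  cfg$rho <- cfg$rho %||% 1060
  cfg$mu <- cfg$mu %||% 3.2e-3
  cfg
}

# Execute one job; returns list(record, row, log_lines).
run_job <- function(job, config, outdir) {
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  logf <- function(...) log_lines <<- c(log_lines, paste0(...))
  result <- tryCatch({
    q <- build_queue(job)
    for (nt in q$notices) logf("[", job$subject_id, "] notice: ", nt)
    cfg <- job_config(config, job$params_override)
    const <- hemo_constants(rho = cfg$rho, mu = cfg$mu)
    jobdir <- file.path(outdir, job$subject_id)
    if (!dir.exists(jobdir)) dir.create(jobdir, recursive = TRUE)
    ctx <- new.env(parent = emptyenv())
    ctx$flags <- character(0)
    timings <- numeric(0)
    if (q$entry == "dicom") {
      ctx$ds <- read_dicom_series(job$data_path)
      ctx$seg <- NULL
    } else {
      got <- read_flow_h5(job$data_path)
      ctx$ds <- got$ds
      ctx$seg <- got$seg
    }
    need_geometry <- function() {
      if (is.null(ctx$cl)) {
        ctx$cl <- extract_centerline(ctx$seg, ctx$ds$header)
        ctx$planes <- place_planes(ctx$cl, cfg$plane_spacing)
        ctx$curves <- flow_time_curves(ctx$ds, ctx$seg, ctx$planes)
      }
    }
    for (step in q$steps) {
      ts <- proc.time()[["elapsed"]]
      switch(step,
        convert = {
          # import already performed; persist the standardized container
          write_flow_h5(ctx$ds, file.path(jobdir, "converted.h5"))
        },
        noise = {
          ctx$noise <- noise_mask(ctx$ds, cfg$preprocess)
          ctx$ds <- apply_noise_mask(ctx$ds, ctx$noise)
          ctx$reports$noise <- list(n_noise_voxels = sum(ctx$noise),
                                    params = unclass(cfg$preprocess))
          logf("[", job$subject_id, "] noise: ", sum(ctx$noise), " voxels masked")
        },
        phase = {
          static <- static_tissue_mask(ctx$ds, cfg$preprocess, noise = ctx$noise)
          got <- correct_background_phase(ctx$ds, static, cfg$preprocess)
          ctx$ds <- got$ds
          ctx$reports$phase <- unclass(got$report)
          logf("[", job$subject_id, "] phase: ", got$report$n_static_voxels,
               " static voxels")
        },
        alias = {
          got <- unwrap_aliasing(ctx$ds, cfg$preprocess)
          ctx$ds <- got$ds
          ctx$reports$alias <- unclass(got$report)
          logf("[", job$subject_id, "] alias: corrections ",
               paste(got$report$n_unwrapped_voxels, collapse = ","))
        },
        noiseai = , phaseai = , aliasai = {
          hook <- .af_state[[step]]
          if (is.null(hook)) af_stop("model not available: ", step)
          ctx$ds <- hook(ctx$ds, ctx)
        },
        seg = {
          ctx$seg <- threshold_segment(compute_pcmra(ctx$ds), ctx$ds,
                                       cfg$seg_fraction)
        },
        regions = {
          need_geometry()
          ctx$seg <- split_aorta_regions(ctx$seg, ctx$cl, ctx$ds$header)
        },
        pwv = , vmax = , ke = , el = {
          need_geometry()
          # quantifications computed together on first request
          if (is.null(ctx$quant)) {
            ctx$quant <- quantify_hemodynamics(
              ctx$ds, ctx$seg, curves = ctx$curves, const = const,
              el_boundary = cfg$el_boundary)
            if (!is.null(ctx$quant$pwv) && !ctx$quant$pwv$reliable) {
              ctx$flags <- c(ctx$flags, "unreliable PWV")
            }
          }
        },
        qc = {
          files <- render_qc(ctx$ds, ctx$seg, ctx$cl, ctx$planes, ctx$curves,
                             jobdir, flags = ctx$flags)
          logf("[", job$subject_id, "] qc: ", length(files), " files")
        }
      )
      timings[step] <- proc.time()[["elapsed"]] - ts
    }
    # machine-readable correction-report sidecar
    if (!is.null(ctx$reports)) {
      writeLines(jsonlite::toJSON(ctx$reports, auto_unbox = TRUE, digits = NA),
                 file.path(jobdir, "preprocess_report.json"))
    }
    # persist the processed dataset + detail results
    h5path <- file.path(jobdir, "processed.h5")
    write_flow_h5(ctx$ds, h5path, seg = ctx$seg)
    if (!is.null(ctx$quant)) h5_write_results(h5path, ctx$quant$detail)
    row <- results_row(job$subject_id, ctx$quant, ctx$flags)
    list(record = run_record(job$subject_id, "success", timings = timings,
                             outputs = jobdir),
         row = row, log_lines = log_lines)
  }, error = function(e) {
    msg <- conditionMessage(e)
    list(record = run_record(job$subject_id, "failed", error = msg),
         row = NULL,
         log_lines = c(log_lines, paste0("[", job$subject_id, "] ERROR: ", msg)))
  })
  result$record$elapsed <- proc.time()[["elapsed"]] - t0
  result
}

# one results-CSV row (wide: regional metrics by region)
results_row <- function(subject_id, quant, flags) {
  row <- tibble::tibble(subject_id = subject_id, status = "success")
  if (!is.null(quant)) {
    if (!is.null(quant$pwv)) {
      row$pwv_m_s <- quant$pwv$pwv
      row$pwv_fit_r2 <- quant$pwv$fit_r2
    }
    reg <- quant$regional
    if (!is.null(reg)) {
      metrics <- setdiff(names(reg), "region")
      for (i in seq_len(nrow(reg))) {
        for (mm in metrics) {
          row[[paste0(mm, "_", reg$region[i])]] <- reg[[mm]][i]
        }
      }
    }
  }
  row$qc_flags <- paste(flags, collapse = ";")
  row
}

#' Run a processing batch
#'
#' Executes the jobs of an input sheet independently and in order:
#' failures are recorded per job and never abort the batch. Writes
#' `results.csv` (one row per successful job), `run.log`, and per-job
#' outputs (processed HDF5, QC images) under `out_dir`. The pipeline
#' contains no randomness, so identical inputs give byte-identical
#' results files on repeat runs.
#'
#' @param sheet input-sheet CSV path, or the list from
#'   [parse_input_sheet()].
#' @param out_dir output directory (created if needed).
#' @param config optional named list of parameter overrides (applied
#'   before per-row `Params`), or a YAML file path.
#' @return A list: `results` (tibble), `records` (all run records),
#'   `summary` ("n success / m failed").
#' @export
run_batch <- function(sheet, out_dir, config = NULL) {
  if (is.character(sheet)) sheet <- parse_input_sheet(sheet)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE)
    if (!ok) af_stop("run_batch: cannot create output directory ", out_dir)
  }
  records <- sheet$failures
  rows <- list()
  log_lines <- vapply(sheet$failures, function(r) {
    paste0("[", r$subject_id, "] ERROR: ", r$error_text)
  }, character(1))
  for (job in sheet$jobs) {
    res <- run_job(job, config, out_dir)
    records[[length(records) + 1]] <- res$record
    if (!is.null(res$row)) rows[[length(rows) + 1]] <- res$row
    log_lines <- c(log_lines, res$log_lines,
                   sprintf("[%s] %s (%.2f s)", res$record$subject_id,
                           res$record$status, res$record$elapsed))
  }
  results <- if (length(rows)) bind_rows_fill(rows) else tibble::tibble()
  n_ok <- sum(vapply(records, function(r) r$status == "success", logical(1)))
  n_fail <- length(records) - n_ok
  summary_line <- sprintf("%d/%d succeeded (%d failed)",
                          n_ok, length(records), n_fail)
  write_results_csv(results, file.path(out_dir, "results.csv"))
  writeLines(c(log_lines, summary_line), file.path(out_dir, "run.log"))
  list(results = results, records = records, summary = summary_line)
}

# rbind tibbles whose columns may differ (missing filled with NA)
bind_rows_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    r[, cols]
  })
  do.call(rbind, rows)
}

# results CSV with stable full-precision number formatting
write_results_csv <- function(df, path) {
  if (nrow(df) == 0) {
    writeLines("subject_id,status", path)
    return(invisible(path))
  }
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bland-Altman agreement statistics
#'
#' Bias is the mean paired difference; the limits of agreement are
#' 1.96 times the sample standard deviation (n-1) of the differences.
#'
#' @param a,b equal-length paired numeric vectors, n >= 2.
#' @return A list of class `bland_altman`: `bias`, `loa`, `n`, `diffs`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) af_stop("bland_altman: unequal lengths")
  if (length(a) < 2) af_stop("bland_altman: need n >= 2 pairs")
  d <- a - b
  structure(list(bias = mean(d), loa = 1.96 * sd(d), n = length(d),
                 diffs = d, means = (a + b) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> n = ", x$n, ", bias = ", fmt_num(x$bias),
      ", LoA = +/-", fmt_num(x$loa), "\n", sep = "")
  invisible(x)
}
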