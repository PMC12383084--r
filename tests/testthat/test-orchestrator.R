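# Input-sheet parsing, queue building, batch execution, QC outputs, and
# the Bland-Altman utility.

write_sheet <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  f <- file.path(dir, "sheet.csv")
  writeLines(c("Subject ID,Data Path,Steps,Params", rows), f)
  f
}

small_phantom_h5 <- function(seed = 1, with_mask = FALSE,
                             dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ph <- generate_phantom(small_phantom_params(seed = seed))
  f <- file.path(dir, sprintf("ph_seed%d_%d.h5", seed, with_mask))
  write_flow_h5(ph$ds, f, seg = if (with_mask) ph$seg)
  f
}

test_that("input sheet parses rows and isolates malformed ones", {
  td <- withr::local_tempdir()
  h5 <- small_phantom_h5(dir = td)
  f <- write_sheet(c(
    sprintf("S01,%s,pwv;noise;seg;alias;el;qc;vmax;phase;ke,", h5),
    sprintf("S02,%s,noise;foo,", h5),
    ",%s,noise,",
    sprintf("S01,%s,noise,", h5),
    sprintf("S03,%s,noise,noise_threshold=0.2;poly_order=1", h5)
  ), dir = td)
  got <- parse_input_sheet(f)
  expect_length(got$jobs, 2)
  expect_length(got$failures, 3)
  # canonical re-ordering regardless of sheet order
  expect_identical(got$jobs[[1]]$steps,
                   c("noise", "phase", "alias", "seg", "pwv", "vmax", "ke",
                     "el", "qc"))
  expect_match(got$failures[[1]]$error_text, "unknown keyword: foo")
  expect_match(got$failures[[3]]$error_text, "duplicate subject id")
  expect_identical(got$jobs[[2]]$params_override$noise_threshold, 0.2)
  expect_identical(got$jobs[[2]]$params_override$poly_order, 1L)
  expect_error(parse_input_sheet(file.path(td, "missing.csv")), "cannot read")
})

test_that("queue building detects the entry point and dependencies", {
  td <- withr::local_tempdir()
  h5_plain <- small_phantom_h5(with_mask = FALSE, dir = td)
  h5_mask <- small_phantom_h5(with_mask = TRUE, dir = td)
  mk_job <- function(path, steps) {
    structure(list(subject_id = "X", data_path = path, steps = steps,
                   params_override = list()), class = "job_spec")
  }
  # already-processed input: preprocessing and segmentation skipped with notice
  q <- build_queue(mk_job(h5_mask, c("noise", "pwv")))
  expect_identical(q$entry, "h5_mask")
  expect_identical(q$steps, "pwv")
  expect_match(paste(q$notices, collapse = "; "), "skipping noise")
  # quantification without any segmentation source fails the build
  expect_error(build_queue(mk_job(h5_plain, c("noise", "pwv"))),
               "segmentation required")
  # regional quantification queues the region split implicitly
  q2 <- build_queue(mk_job(h5_plain, c("seg", "vmax")))
  expect_true("regions" %in% q2$steps)
  expect_error(build_queue(mk_job(file.path(td, "nope.xyz"), "noise")),
               "entry point")
})

test_that("AI keywords dispatch to the plug-in hook", {
  td <- withr::local_tempdir()
  h5 <- small_phantom_h5(dir = td)
  f <- write_sheet(sprintf("S01,%s,noiseai,", h5), dir = td)
  out <- file.path(td, "out_ai")
  res <- run_batch(f, out)
  expect_identical(res$records[[1]]$status, "failed")
  expect_match(res$records[[1]]$error_text, "model not available: noiseai")
  # a registered plug-in makes the step succeed
  old <- register_ai_module("noiseai", function(ds, ctx) ds)
  withr::defer(register_ai_module("noiseai", old))
  res2 <- run_batch(f, file.path(td, "out_ai2"))
  expect_identical(res2$records[[1]]$status, "success")
})

test_that("batch isolates failures and reruns are byte-identical", {
  td <- withr::local_tempdir()
  h5a <- small_phantom_h5(seed = 1, dir = td)
  h5b <- small_phantom_h5(seed = 2, dir = td)
  corrupt <- file.path(td, "corrupt.h5")
  writeLines("not hdf5", corrupt)
  steps <- "noise;phase;alias;seg;regions;pwv;vmax;ke;el;qc"
  f <- write_sheet(c(
    sprintf("S01,%s,%s,", h5a, steps),
    sprintf("S02,%s,%s,", corrupt, steps),
    sprintf("S03,%s,%s,", h5b, steps)
  ), dir = td)
  out1 <- file.path(td, "out1")
  res <- run_batch(f, out1)
  status <- vapply(res$records, function(r) r$status, character(1))
  ids <- vapply(res$records, function(r) r$subject_id, character(1))
  expect_identical(status[match(c("S01", "S02", "S03"), ids)],
                   c("success", "failed", "success"))
  expect_identical(nrow(res$results), 2L)
  expect_match(res$summary, "2/3")
  # repeat run: results CSV and QC images byte-identical
  out2 <- file.path(td, "out2")
  run_batch(f, out2)
  expect_identical(readLines(file.path(out1, "results.csv")),
                   readLines(file.path(out2, "results.csv")))
  pngs1 <- sort(list.files(file.path(out1, "S01"), pattern = "\\.png$",
                           full.names = TRUE))
  pngs2 <- sort(list.files(file.path(out2, "S01"), pattern = "\\.png$",
                           full.names = TRUE))
  expect_identical(unname(tools::md5sum(pngs1)), unname(tools::md5sum(pngs2)))
  # row order invariance: permuting sheet rows permutes, not changes, results
  f_perm <- write_sheet(c(
    sprintf("S03,%s,%s,", h5b, steps),
    sprintf("S01,%s,%s,", h5a, steps)
  ), dir = td)
  res_perm <- run_batch(f_perm, file.path(td, "out3"))
  a <- res$results[res$results$subject_id == "S03", ]
  b <- res_perm$results[res_perm$results$subject_id == "S03", ]
  expect_equal(as.list(a), as.list(b))
})

test_that("empty job lists produce an empty summary", {
  td <- withr::local_tempdir()
  f <- write_sheet(character(0), dir = td)
  res <- run_batch(f, file.path(td, "out"))
  expect_match(res$summary, "0/0")
  expect_identical(nrow(res$results), 0L)
})

test_that("run records are conserved: one per parsed row", {
  td <- withr::local_tempdir()
  h5 <- small_phantom_h5(dir = td)
  f <- write_sheet(c(
    sprintf("A,%s,qc,", h5),
    sprintf("B,%s,badkw,", h5),
    sprintf("C,%s,qc,", h5)
  ), dir = td)
  res <- run_batch(f, file.path(td, "out"))
  expect_length(res$records, 3)
  ids <- sort(vapply(res$records, function(r) r$subject_id, character(1)))
  expect_identical(ids, c("A", "B", "C"))
})

test_that("QC rendering writes deterministic panels and a verdict stub", {
  ph <- small_phantom()
  cl <- extract_centerline(ph$seg, ph$ds$header)
  planes <- place_planes(cl, 25)
  curves <- flow_time_curves(ph$ds, ph$seg, planes)
  d1 <- withr::local_tempdir()
  files <- render_qc(ph$ds, ph$seg, cl, planes, curves, d1)
  expect_setequal(basename(files), c("qc_overlay.png", "qc_render.png",
                                     "qc_curves.png", "qc_verdict.json"))
  verdict <- jsonlite::read_json(file.path(d1, "qc_verdict.json"))
  expect_identical(verdict$review, "pending")
  # without a segmentation only the magnitude panel is written, with a note
  d2 <- withr::local_tempdir()
  files2 <- render_qc(ph$ds, NULL, NULL, NULL, NULL, d2)
  expect_true("qc_overlay.png" %in% basename(files2))
  expect_false("qc_render.png" %in% basename(files2))
  v2 <- jsonlite::read_json(file.path(d2, "qc_verdict.json"))
  expect_gt(length(v2$skipped_panels), 0)
})

test_that("Bland-Altman statistics match hand-computed values", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_identical(ba0$bias, 0)
  expect_identical(ba0$loa, 0)
  ba <- bland_altman(c(1, 0), c(0, 1))  # differences +1, -1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_error(bland_altman(1, 1), "n >= 2")
  expect_error(bland_altman(1:3, 1:2), "unequal")
  gl <- generics::glance(ba)
  expect_identical(gl$n, 2L)
})
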