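# Classic single-frame DICOM import/export (explicit VR little endian).
#
# The package defines its own minimal classic-DICOM dialect: one magnitude
# series plus three velocity-encoded series, one file per slice and
# timeframe, sorted by (slice location, trigger time). Velocity phase maps
# linearly to the VENC range (phase pi <-> VENC) through Rescale
# Slope/Intercept with 12-bit quantization, so |quantization error| <=
# VENC/2048. Scan parameters that classic DICOM has no public tag for
# (VENC, temporal resolution, component label) travel in a private group
# 0019 block with creator "AORTAFLOW". Enhanced multi-frame DICOM is out
# of scope.

u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

dcm_elem <- function(group, elem, vr, value) {
  bytes <- switch(vr,
    US = u16raw(value),
    UL = u32raw(value),
    OW = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UI = dcm_pad(charToRaw(as.character(value)), as.raw(0)),
    dcm_pad(charToRaw(as.character(value)))  # DS/IS/CS/LO and other strings
  )
  hdr <- c(u16raw(group), u16raw(elem), charToRaw(vr))
  if (vr %in% .vr_long) {
    c(hdr, raw(2), u32raw(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534) af_stop("dicom: element too long for short VR")
    c(hdr, u16raw(length(bytes)), bytes)
  }
}

dcm_file_meta <- function(sop_uid) {
  body <- c(
    dcm_elem(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.4"),
    dcm_elem(0x0002, 0x0003, "UI", sop_uid),
    dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  c(raw(128), charToRaw("DICM"),
    dcm_elem(0x0002, 0x0000, "UL", length(body)), body)
}

ds_str <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

# Write one single-frame slice file.
write_dicom_slice <- function(path, pixels_u16, meta) {
  sop <- sprintf("1.2.826.0.1.3680043.9.7433.%d.%d.%d",
                 meta$series_number, meta$z, meta$t)
  series_uid <- sprintf("1.2.826.0.1.3680043.9.7433.%d", meta$series_number)
  el <- c(
    dcm_file_meta(sop),
    dcm_elem(0x0008, 0x0018, "UI", sop),
    dcm_elem(0x0008, 0x0060, "CS", "MR"),
    dcm_elem(0x0008, 0x103E, "LO", meta$series_description),
    dcm_elem(0x0018, 0x0050, "DS", ds_str(meta$slice_thickness)),
    dcm_elem(0x0018, 0x1060, "DS", ds_str(meta$trigger_time)),
    dcm_elem(0x0019, 0x0010, "LO", "AORTAFLOW"),
    if (!is.null(meta$venc)) dcm_elem(0x0019, 0x1001, "DS", ds_str(meta$venc)),
    dcm_elem(0x0019, 0x1002, "CS", meta$component),
    dcm_elem(0x0019, 0x1003, "DS", ds_str(meta$temporal_resolution)),
    dcm_elem(0x0020, 0x000E, "UI", series_uid),
    dcm_elem(0x0020, 0x0011, "IS", as.character(meta$series_number)),
    dcm_elem(0x0020, 0x0013, "IS", as.character(meta$instance_number)),
    dcm_elem(0x0020, 0x0032, "DS", ds_str(meta$position)),
    dcm_elem(0x0020, 0x0037, "DS", ds_str(meta$orientation)),
    dcm_elem(0x0020, 0x1041, "DS", ds_str(meta$slice_location)),
    dcm_elem(0x0028, 0x0002, "US", 1L),
    dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_elem(0x0028, 0x0010, "US", meta$rows),
    dcm_elem(0x0028, 0x0011, "US", meta$cols),
    dcm_elem(0x0028, 0x0030, "DS", ds_str(meta$pixel_spacing)),
    dcm_elem(0x0028, 0x0100, "US", 16L),
    dcm_elem(0x0028, 0x0101, "US", 16L),
    dcm_elem(0x0028, 0x0102, "US", 15L),
    dcm_elem(0x0028, 0x0103, "US", 0L),
    dcm_elem(0x0028, 0x1052, "DS", ds_str(meta$intercept)),
    dcm_elem(0x0028, 0x1053, "DS", ds_str(meta$slope)),
    dcm_elem(0x7FE0, 0x0010, "OW", pixels_u16)
  )
  writeBin(el, path)
}

# Parse one explicit-VR-little-endian file into a tag -> value list.
parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 200 || rawToChar(bytes[129:132]) != "DICM") {
    af_stop("not a DICOM file: ", path)
  }
  pos <- 133L
  n <- length(bytes)
  out <- list()
  rd_u16 <- function(at) readBin(bytes[at:(at + 1)], "integer", size = 2,
                                 endian = "little", signed = FALSE)
  rd_u32 <- function(at) readBin(bytes[at:(at + 3)], "integer", size = 4,
                                 endian = "little")
  while (pos + 7 <= n) {
    group <- rd_u16(pos); elem <- rd_u16(pos + 2)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% .vr_long) {
      len <- rd_u32(pos + 8); vstart <- pos + 12
    } else {
      len <- rd_u16(pos + 6); vstart <- pos + 8
    }
    val_bytes <- if (len > 0) bytes[vstart:(vstart + len - 1)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, bytes = val_bytes)
    pos <- vstart + len
  }
  out
}

tag_str <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  trimws(rawToChar(el[[key]]$bytes))
}

tag_ds <- function(el, key) {
  s <- tag_str(el, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

tag_us <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  readBin(el[[key]]$bytes, "integer", size = 2, endian = "little", signed = FALSE)
}

tag_pixels <- function(el) {
  b <- el[["7FE0,0010"]]
  if (is.null(b)) af_stop("dicom: missing PixelData")
  readBin(b$bytes, "integer", n = length(b$bytes) / 2, size = 2,
          endian = "little", signed = FALSE)
}

#' Import a 4D flow acquisition from classic DICOM series
#'
#' Assembles one magnitude and three velocity-encoded single-frame series
#' (one file per slice and timeframe) into a [flow_dataset()]. Files are
#' ordered by their metadata (slice location, then trigger time), never by
#' filename, and phase data are rescaled to velocity in m/s with phase pi
#' corresponding to VENC.
#'
#' @param directory directory containing the DICOM files of all 4 series.
#' @return A [flow_dataset()].
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory)) af_stop("read_dicom_series: no such directory: ", directory)
  files <- sort(list.files(directory, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0) af_stop("read_dicom_series: directory is empty")
  recs <- lapply(files, function(f) {
    el <- parse_dicom_file(f)
    list(
      component = tag_str(el, "0019,1002") %||% NA_character_,
      desc = tag_str(el, "0008,103E") %||% "",
      venc = tag_ds(el, "0019,1001"),
      tres = tag_ds(el, "0019,1003"),
      slice_location = tag_ds(el, "0020,1041"),
      trigger = tag_ds(el, "0018,1060") %||% 0,
      position = tag_ds(el, "0020,0032"),
      orientation = tag_ds(el, "0020,0037"),
      pixel_spacing = tag_ds(el, "0028,0030"),
      thickness = tag_ds(el, "0018,0050"),
      rows = tag_us(el, "0028,0010"),
      cols = tag_us(el, "0028,0011"),
      slope = tag_ds(el, "0028,1053") %||% 1,
      intercept = tag_ds(el, "0028,1052") %||% 0,
      pixels = tag_pixels(el)
    )
  })
  comp <- vapply(recs, function(r) r$component, character(1))
  series <- list()
  for (cc in c("MAG", "VX", "VY", "VZ")) series[[cc]] <- recs[comp == cc]
  if (length(series$MAG) == 0) af_stop("read_dicom_series: magnitude series missing")
  for (cc in c("VX", "VY", "VZ")) {
    if (length(series[[cc]]) == 0) {
      af_stop("read_dicom_series: velocity series missing (component ", cc, ")")
    }
  }

  assemble <- function(rs, what) {
    desc <- rs[[1]]$desc
    zs <- sort(unique(vapply(rs, function(r) r$slice_location, numeric(1))))
    ts <- sort(unique(vapply(rs, function(r) r$trigger, numeric(1))))
    if (length(rs) != length(zs) * length(ts)) {
      af_stop("read_dicom_series: inconsistent slice counts per timeframe in series '",
              desc, "' (", length(rs), " files for ", length(zs), " slices x ",
              length(ts), " timeframes)")
    }
    nx <- rs[[1]]$cols; ny <- rs[[1]]$rows
    arr <- array(NA_real_, c(nx, ny, length(zs), length(ts)))
    seen <- array(FALSE, c(length(zs), length(ts)))
    for (r in rs) {
      iz <- match(r$slice_location, zs)
      it <- match(r$trigger, ts)
      if (seen[iz, it]) {
        af_stop("read_dicom_series: duplicate slice/timeframe in series '", desc, "'")
      }
      seen[iz, it] <- TRUE
      if (r$cols != nx || r$rows != ny) {
        af_stop("read_dicom_series: inconsistent matrix size in series '", desc, "'")
      }
      arr[, , iz, it] <- matrix(r$pixels * r$slope + r$intercept, nrow = nx)
    }
    list(arr = arr, zs = zs, ts = ts, ref = rs[[which.min(vapply(
      rs, function(r) r$slice_location * 1e6 + r$trigger, numeric(1)))]])
  }

  mag <- assemble(series$MAG, "magnitude")
  vel <- lapply(c("VX", "VY", "VZ"), function(cc) {
    s <- assemble(series[[cc]], cc)
    if (is.null(s$ref$venc)) {
      af_stop("read_dicom_series: missing VENC tag in series '", s$ref$desc, "'")
    }
    s
  })
  dims <- dim(mag$arr)
  for (s in vel) {
    if (!all(dim(s$arr) == dims)) {
      af_stop("read_dicom_series: series grids disagree: magnitude ",
              paste(dims, collapse = "x"), " vs '", s$ref$desc, "' ",
              paste(dim(s$arr), collapse = "x"))
    }
  }
  vencs <- vapply(vel, function(s) s$ref$venc, numeric(1))
  if (max(vencs) - min(vencs) > 1e-9) {
    af_stop("read_dicom_series: VENC differs across velocity series")
  }
  venc <- vencs[1]

  ref <- mag$ref
  dz <- if (length(mag$zs) > 1) mean(diff(mag$zs)) else (ref$thickness %||% 1)
  tres <- ref$tres %||% (if (length(mag$ts) > 1) mean(diff(mag$ts)) else 1)
  iop <- ref$orientation %||% c(1, 0, 0, 0, 1, 0)
  xdir <- iop[1:3]; ydir <- iop[4:6]
  zdir <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
            xdir[3] * ydir[1] - xdir[1] * ydir[3],
            xdir[1] * ydir[2] - xdir[2] * ydir[1])
  ps <- ref$pixel_spacing %||% c(1, 1)  # (row spacing = Y, column spacing = X)
  header <- scan_header(
    voxel_size = c(ps[2], ps[1], dz),
    temporal_resolution = tres,
    origin = ref$position %||% c(0, 0, 0),
    axis_orientation = rbind(xdir, ydir, zdir),
    venc = venc,
    n_timeframes = dims[4]
  )
  velocity <- array(0, c(dims, 3))
  for (k in 1:3) velocity[, , , , k] <- vel[[k]]$arr / 100  # cm/s -> m/s
  ds <- flow_dataset(mag$arr, velocity, header)
  validate_flow_dataset(ds, venc_bound = TRUE)
  ds
}

#' Export a 4D flow dataset as classic DICOM series
#'
#' Writes one magnitude and three velocity-encoded single-frame series
#' (file count = Z x T x 4) in the dialect [read_dicom_series()] imports.
#' Velocity is stored as 12-bit phase with phase pi corresponding to VENC;
#' components beyond +/-VENC wrap around, exactly as aliased acquisitions
#' do.
#'
#' @param ds a [flow_dataset()].
#' @param directory output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
export_phantom_dicom <- function(ds, directory) {
  validate_flow_dataset(ds)
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  h <- ds$header
  d <- dim(ds$magnitude)
  venc <- h$venc
  mag_slope <- max(ds$magnitude) / 4095
  if (mag_slope == 0) mag_slope <- 1
  comps <- c("MAG", "VX", "VY", "VZ")
  descs <- c("magnitude", "velocity_x", "velocity_y", "velocity_z")
  zdir <- h$axis_orientation[3, ]
  base_loc <- sum(h$origin * zdir)
  written <- character(0)
  for (si in seq_along(comps)) {
    for (iz in seq_len(d[3])) {
      for (it in seq_len(d[4])) {
        if (si == 1) {
          u <- round(ds$magnitude[, , iz, it] / mag_slope)
          slope <- mag_slope; intercept <- 0
        } else {
          v_cm <- ds$velocity[, , iz, it, si - 1] * 100
          frac <- ((v_cm / venc + 1) %% 2) - 1   # wrap to [-1, 1)
          u <- round((frac + 1) * 2048) %% 4096
          slope <- venc / 2048; intercept <- -venc
        }
        meta <- list(
          series_number = si,
          series_description = descs[si],
          component = comps[si],
          venc = if (si > 1) venc else NULL,
          temporal_resolution = h$temporal_resolution,
          z = iz, t = it,
          instance_number = (iz - 1) * d[4] + it,
          slice_thickness = h$voxel_size[3],
          trigger_time = (it - 1) * h$temporal_resolution,
          position = h$origin + (iz - 1) * h$voxel_size[3] * zdir,
          orientation = c(h$axis_orientation[1, ], h$axis_orientation[2, ]),
          slice_location = base_loc + (iz - 1) * h$voxel_size[3],
          rows = d[2], cols = d[1],
          pixel_spacing = c(h$voxel_size[2], h$voxel_size[1]),
          slope = slope, intercept = intercept
        )
        f <- file.path(directory, sprintf("%s_z%03d_t%03d.dcm",
                                          tolower(comps[si]), iz, it))
        write_dicom_slice(f, as.integer(u), meta)
        written <- c(written, f)
      }
    }
  }
  invisible(written)
}
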