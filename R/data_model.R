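# Standardized dataset container: scan header, 4D flow dataset,
# segmentation mask, and the compressed HDF5 reader/writer.

#' Construct a scan header
#'
#' The header carries the essential acquisition parameters of a 4D flow
#' scan: voxel size, temporal resolution, the physical position of voxel
#' (0,0,0), the direction cosines of the three array axes, and the
#' velocity-encoding limit (VENC).
#'
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param temporal_resolution scalar, time between frames in ms.
#' @param venc scalar velocity-encoding limit in cm/s.
#' @param n_timeframes integer number of cardiac timeframes.
#' @param origin numeric length-3, physical position (mm) of voxel index
#'   (0,0,0).
#' @param axis_orientation 3x3 matrix of direction cosines; row i is the
#'   physical direction of array axis i. Rows must be unit-norm and
#'   mutually orthogonal.
#' @return An object of class `scan_header`.
#' @export
scan_header <- function(voxel_size, temporal_resolution, venc, n_timeframes,
                        origin = c(0, 0, 0), axis_orientation = diag(3)) {
  h <- structure(
    list(
      voxel_size = as.numeric(voxel_size),
      temporal_resolution = as.numeric(temporal_resolution),
      origin = as.numeric(origin),
      axis_orientation = matrix(as.numeric(axis_orientation), 3, 3),
      venc = as.numeric(venc),
      n_timeframes = as.integer(n_timeframes)
    ),
    class = "scan_header"
  )
  validate_scan_header(h)
  h
}

#' Validate a scan header
#'
#' Checks positivity of voxel size, temporal resolution and VENC, and that
#' the direction-cosine rows are unit-norm and mutually orthogonal within
#' 1e-6.
#'
#' @param h a `scan_header`.
#' @return `h`, invisibly; errors on violation.
#' @export
validate_scan_header <- function(h) {
  if (length(h$voxel_size) != 3 || any(h$voxel_size <= 0)) {
    af_stop("scan_header: voxel_size must be 3 positive values (mm)")
  }
  if (length(h$temporal_resolution) != 1 || h$temporal_resolution <= 0) {
    af_stop("scan_header: temporal_resolution must be a positive scalar (ms)")
  }
  if (length(h$venc) != 1 || h$venc <= 0) {
    af_stop("scan_header: venc must be a positive scalar (cm/s)")
  }
  if (length(h$origin) != 3) af_stop("scan_header: origin must be a 3-vector (mm)")
  A <- h$axis_orientation
  if (any(abs(sqrt(rowSums(A^2)) - 1) > 1e-6)) {
    af_stop("scan_header: axis_orientation rows must be unit-norm")
  }
  G <- A %*% t(A)
  if (any(abs(G - diag(3)) > 1e-6)) {
    af_stop("scan_header: axis_orientation rows must be mutually orthogonal")
  }
  if (is.na(h$n_timeframes) || h$n_timeframes < 1) {
    af_stop("scan_header: n_timeframes must be a positive integer")
  }
  invisible(h)
}

# VENC converted to m/s for internal use.
venc_ms <- function(h) h$venc / 100

#' Construct a 4D flow dataset
#'
#' The central container: a magnitude image series `[X,Y,Z,T]` (arbitrary
#' units, non-negative), a velocity field `[X,Y,Z,T,3]` in m/s with
#' components along the header axes, and the scan header.
#'
#' @param magnitude numeric array `[X,Y,Z,T]`.
#' @param velocity numeric array `[X,Y,Z,T,3]`, m/s.
#' @param header a [scan_header()].
#' @return An object of class `flow_dataset`.
#' @export
flow_dataset <- function(magnitude, velocity, header) {
  ds <- structure(
    list(magnitude = magnitude, velocity = velocity, header = header),
    class = "flow_dataset"
  )
  validate_flow_dataset(ds)
  ds
}

#' Validate a 4D flow dataset
#'
#' Checks that magnitude and velocity agree on `[X,Y,Z,T]`, that T matches
#' the header, that the magnitude is non-negative and all values finite.
#' With `venc_bound = TRUE` (used on freshly imported phase data, where the
#' phase range caps speeds) it additionally checks that every velocity
#' component satisfies |v| <= VENC + 1e-9 in m/s; corrected (anti-aliased)
#' data may legitimately exceed VENC and are not checked.
#'
#' @param ds a `flow_dataset`.
#' @param venc_bound check the per-component VENC bound (default `FALSE`).
#' @return `ds`, invisibly; errors on violation.
#' @export
validate_flow_dataset <- function(ds, venc_bound = FALSE) {
  dm <- dim(ds$magnitude)
  dv <- dim(ds$velocity)
  if (length(dm) != 4) af_stop("flow_dataset: magnitude must be [X,Y,Z,T]")
  if (length(dv) != 5 || dv[5] != 3) af_stop("flow_dataset: velocity must be [X,Y,Z,T,3]")
  if (!all(dm == dv[1:4])) {
    af_stop("flow_dataset: magnitude ", paste(dm, collapse = "x"),
            " and velocity ", paste(dv[1:4], collapse = "x"),
            " disagree on [X,Y,Z,T]")
  }
  validate_scan_header(ds$header)
  if (dm[4] != ds$header$n_timeframes) {
    af_stop("flow_dataset: T = ", dm[4], " but header n_timeframes = ",
            ds$header$n_timeframes)
  }
  if (min(ds$magnitude) < 0) af_stop("flow_dataset: magnitude must be >= 0")
  if (anyNA(ds$velocity) || anyNA(ds$magnitude)) af_stop("flow_dataset: non-finite values")
  if (venc_bound) {
    vmax <- max(abs(ds$velocity))
    if (vmax > venc_ms(ds$header) + 1e-9) {
      af_stop("flow_dataset: velocity component ", fmt_num(vmax),
              " m/s exceeds VENC ", fmt_num(venc_ms(ds$header)), " m/s")
    }
  }
  invisible(ds)
}

#' @export
print.flow_dataset <- function(x, ...) {
  d <- dim(x$magnitude)
  cat("<flow_dataset> ", paste(d[1:3], collapse = "x"), " voxels, ",
      d[4], " timeframes\n", sep = "")
  cat("  voxel size: ", paste(fmt_num(x$header$voxel_size), collapse = " x "),
      " mm; dt: ", fmt_num(x$header$temporal_resolution), " ms; VENC: ",
      fmt_num(x$header$venc), " cm/s\n", sep = "")
  invisible(x)
}

#' Construct an aortic segmentation mask
#'
#' @param whole logical array `[X,Y,Z]`: the whole-aorta mask.
#' @param regions optional integer array `[X,Y,Z]` with labels 0 (outside),
#'   1 (ascending aorta), 2 (arch), 3 (descending aorta). Must be nonzero
#'   exactly where `whole` is `TRUE`.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(whole, regions = NULL) {
  m <- structure(list(whole = whole, regions = regions), class = "segmentation_mask")
  validate_segmentation_mask(m)
  m
}

#' Validate a segmentation mask
#'
#' @param m a `segmentation_mask`.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_segmentation_mask <- function(m) {
  if (length(dim(m$whole)) != 3 || !is.logical(m$whole)) {
    af_stop("segmentation_mask: whole must be a logical [X,Y,Z] array")
  }
  if (!is.null(m$regions)) {
    if (!all(dim(m$regions) == dim(m$whole))) {
      af_stop("segmentation_mask: regions grid does not match whole")
    }
    if (!all((m$regions != 0L) == m$whole)) {
      af_stop("segmentation_mask: regions must be nonzero exactly where whole is TRUE")
    }
    if (!all(m$regions %in% 0:3)) {
      af_stop("segmentation_mask: region labels must be in {0,1,2,3}")
    }
  }
  invisible(m)
}

#' Region label codes
#'
#' Named integer codes used in the `regions` array of a
#' [segmentation_mask()]: ascending aorta (AAo) = 1, arch = 2, descending
#' aorta (DAo) = 3.
#' @export
region_codes <- function() c(AAo = 1L, arch = 2L, DAo = 3L)

# ---------------------------------------------------------------------------
# HDF5 container. Fixed layout:
#   /magnitude [X,Y,Z,T]; /velocity [X,Y,Z,T,3];
#   /segmentation/whole, /segmentation/regions (optional);
#   root attributes: voxel_size_mm, temporal_resolution_ms, origin_mm,
#   axis_orientation, venc_cm_s.

h5_chunk <- function(dims) pmin(dims, c(32, 32, 32, 4, 3)[seq_along(dims)])

h5_put <- function(path, name, data, level = 4) {
  dims <- dim(data) %||% length(data)
  storage <- if (is.double(data)) "double" else "integer"
  rhdf5::h5createDataset(path, name, dims = dims, storage.mode = storage,
                         chunk = h5_chunk(dims), level = level)
  rhdf5::h5write(data, path, name)
}

#' Write a 4D flow dataset to the compressed HDF5 container
#'
#' Stores magnitude, velocity, an optional segmentation, and the header as
#' root attributes in a single gzip-compressed HDF5 file. The layout is
#' fixed (`/magnitude`, `/velocity`, `/segmentation/whole`,
#' `/segmentation/regions`, root attributes `voxel_size_mm`,
#' `temporal_resolution_ms`, `origin_mm`, `axis_orientation`, `venc_cm_s`)
#' so that [read_flow_h5()] reproduces the dataset bit-exactly.
#'
#' @param ds a [flow_dataset()].
#' @param path output file path (overwritten if present).
#' @param seg optional [segmentation_mask()].
#' @param compression gzip level 0-9 (default 1; constant-background 4D
#'   flow volumes compress by an order of magnitude already at the fastest
#'   level).
#' @return `path`, invisibly.
#' @export
write_flow_h5 <- function(ds, path, seg = NULL, compression = 1) {
  validate_flow_dataset(ds)
  if (!is.null(seg)) {
    validate_segmentation_mask(seg)
    if (!all(dim(seg$whole) == dim(ds$magnitude)[1:3])) {
      af_stop("write_flow_h5: segmentation grid does not match dataset")
    }
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) af_stop("write_flow_h5: directory does not exist: ", dir)
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) af_stop("write_flow_h5: cannot create ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5_put(path, "magnitude", ds$magnitude, compression)
  h5_put(path, "velocity", ds$velocity, compression)
  if (!is.null(seg)) {
    rhdf5::h5createGroup(path, "segmentation")
    h5_put(path, "segmentation/whole", array(as.integer(seg$whole), dim(seg$whole)),
           compression)
    if (!is.null(seg$regions)) {
      h5_put(path, "segmentation/regions",
             array(as.integer(seg$regions), dim(seg$regions)), compression)
    }
  }
  fid <- rhdf5::H5Fopen(path)
  h <- ds$header
  rhdf5::h5writeAttribute(h$voxel_size, fid, "voxel_size_mm")
  rhdf5::h5writeAttribute(h$temporal_resolution, fid, "temporal_resolution_ms")
  rhdf5::h5writeAttribute(h$origin, fid, "origin_mm")
  rhdf5::h5writeAttribute(h$axis_orientation, fid, "axis_orientation")
  rhdf5::h5writeAttribute(h$venc, fid, "venc_cm_s")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a 4D flow dataset from the HDF5 container
#'
#' @param path file written by [write_flow_h5()] (or conforming to its
#'   documented layout).
#' @return A list with elements `ds` (a [flow_dataset()]) and `seg` (a
#'   [segmentation_mask()] or `NULL` when the file has no segmentation).
#' @export
read_flow_h5 <- function(path) {
  if (!file.exists(path)) af_stop("read_flow_h5: no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  names_present <- file.path(ls$group, ls$name)
  names_present <- sub("^//", "/", names_present)
  need <- c("/magnitude", "/velocity")
  missing_ds <- setdiff(need, names_present)
  attrs <- rhdf5::h5readAttributes(path, "/")
  need_attr <- c("voxel_size_mm", "temporal_resolution_ms", "origin_mm",
                 "axis_orientation", "venc_cm_s")
  missing_attr <- setdiff(need_attr, names(attrs))
  if (length(missing_ds) || length(missing_attr)) {
    af_stop("read_flow_h5: missing required entries: ",
            paste(c(missing_ds, missing_attr), collapse = ", "))
  }
  magnitude <- rhdf5::h5read(path, "magnitude")
  velocity <- rhdf5::h5read(path, "velocity")
  header <- scan_header(
    voxel_size = as.numeric(attrs$voxel_size_mm),
    temporal_resolution = as.numeric(attrs$temporal_resolution_ms),
    origin = as.numeric(attrs$origin_mm),
    axis_orientation = matrix(as.numeric(attrs$axis_orientation), 3, 3),
    venc = as.numeric(attrs$venc_cm_s),
    n_timeframes = dim(magnitude)[4]
  )
  ds <- flow_dataset(magnitude, velocity, header)
  seg <- NULL
  if ("/segmentation/whole" %in% names_present) {
    whole <- rhdf5::h5read(path, "segmentation/whole")
    whole <- array(whole != 0L, dim(whole))
    if (!all(dim(whole) == dim(magnitude)[1:3])) {
      af_stop("read_flow_h5: segmentation grid ", paste(dim(whole), collapse = "x"),
              " does not match dataset ", paste(dim(magnitude)[1:3], collapse = "x"))
    }
    regions <- NULL
    if ("/segmentation/regions" %in% names_present) {
      regions <- rhdf5::h5read(path, "segmentation/regions")
      regions <- array(as.integer(regions), dim(regions))
    }
    seg <- segmentation_mask(whole, regions)
  }
  list(ds = ds, seg = seg)
}

# Does an HDF5 container include a segmentation?
h5_has_mask <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  any(ls$group == "/segmentation" & ls$name == "whole")
}

# Append hemodynamic detail results (time series, delays) under /results.
h5_write_results <- function(path, detail) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  if (!any(ls$group == "/" & ls$name == "results")) {
    rhdf5::h5createGroup(path, "results")
  }
  for (nm in names(detail)) {
    val <- detail[[nm]]
    if (is.numeric(val) && length(val) > 0) {
      rhdf5::h5write(as.numeric(val), path, file.path("results", nm))
    }
  }
  invisible(path)
}
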