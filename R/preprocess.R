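# Traditional (non-AI) preprocessing with pre-defined fixed thresholds:
# noise masking, polynomial background phase-offset correction, and
# fixed-iteration temporal anti-aliasing. Canonical order within the
# pipeline: noise -> phase -> alias.

#' Preprocessing parameters
#'
#' The correction thresholds are fixed, pre-defined values exposed here
#' (and echoed into every [correction report][correct_background_phase])
#' for reproducibility.
#'
#' @param noise_threshold fraction of the maximum time-averaged magnitude
#'   below which a voxel is considered noise (default 0.10).
#' @param static_sd_threshold fraction of VENC bounding the temporal
#'   velocity standard deviation of static tissue (default 0.05).
#' @param poly_order polynomial order of the background phase fit, one of
#'   1, 2, 3 (default 2).
#' @param alias_iterations number of anti-aliasing passes (default 4).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(noise_threshold = 0.10,
                              static_sd_threshold = 0.05,
                              poly_order = 2,
                              alias_iterations = 4) {
  stopifnot(noise_threshold > 0, static_sd_threshold > 0,
            poly_order %in% 1:3, alias_iterations >= 1)
  structure(list(noise_threshold = noise_threshold,
                 static_sd_threshold = static_sd_threshold,
                 poly_order = as.integer(poly_order),
                 alias_iterations = as.integer(alias_iterations)),
            class = "preprocess_params")
}

# Time-averaged magnitude volume.
time_avg_magnitude <- function(ds) {
  d <- dim(ds$magnitude)
  array(rowMeans(matrix(ds$magnitude, prod(d[1:3]), d[4])), d[1:3])
}

#' Threshold-based noise mask
#'
#' Flags voxels whose time-averaged magnitude falls below
#' `noise_threshold` times the maximum time-averaged magnitude.
#'
#' @param ds a [flow_dataset()].
#' @param p a [preprocess_params()].
#' @return Logical array `[X,Y,Z]`, `TRUE` at noise voxels.
#' @export
noise_mask <- function(ds, p = preprocess_params()) {
  avg <- time_avg_magnitude(ds)
  mx <- max(avg)
  if (mx <= 0) af_stop("noise_mask: degenerate magnitude (all zero)")
  avg < p$noise_threshold * mx
}

#' Zero the velocity of noise voxels
#'
#' @param ds a [flow_dataset()].
#' @param mask logical `[X,Y,Z]` noise mask from [noise_mask()].
#' @return The dataset with velocity set to 0 at masked voxels.
#' @export
apply_noise_mask <- function(ds, mask) {
  d <- dim(ds$velocity)
  v <- matrix(ds$velocity, prod(d[1:3]), d[4] * 3)
  v[as.vector(mask), ] <- 0
  ds$velocity <- array(v, d)
  ds
}

#' Static-tissue mask from temporal velocity stability
#'
#' Flags voxels whose temporal velocity standard deviation is below
#' `static_sd_threshold * VENC` for all three components, excluding noise
#' voxels. These voxels anchor the background phase fit.
#'
#' @param ds a [flow_dataset()].
#' @param p a [preprocess_params()].
#' @param noise optional precomputed noise mask (default: computed here).
#' @return Logical array `[X,Y,Z]`.
#' @export
static_tissue_mask <- function(ds, p = preprocess_params(), noise = NULL) {
  d <- dim(ds$velocity)
  if (d[4] < 2) af_stop("static_tissue_mask: at least 2 timeframes required")
  noise <- noise %||% noise_mask(ds, p)
  thr <- p$static_sd_threshold * venc_ms(ds$header)
  static <- !noise
  for (k in 1:3) {
    acc <- ds$velocity[, , , 1, k]
    acc2 <- acc^2
    for (tt in 2:d[4]) {
      sl <- ds$velocity[, , , tt, k]
      acc <- acc + sl
      acc2 <- acc2 + sl^2
    }
    varv <- pmax(acc2 - acc^2 / d[4], 0) / (d[4] - 1)
    static <- static & (sqrt(varv) < thr)
  }
  static
}

#' Background phase-offset correction by polynomial fit over static tissue
#'
#' For each velocity component independently, fits a 3D polynomial of the
#' configured order (in physical mm coordinates) to the time-averaged
#' velocity over static-tissue voxels by least squares, then subtracts the
#' fitted field from every timeframe. Eddy-current-like offsets that are
#' spatially smooth are removed exactly up to the fit order.
#'
#' @param ds a [flow_dataset()].
#' @param static logical `[X,Y,Z]` static-tissue mask.
#' @param p a [preprocess_params()].
#' @return A list: `ds` (corrected dataset) and `report` (a
#'   `correction_report` carrying the fitted coefficients, their monomial
#'   exponents, counts and the parameters used).
#' @export
correct_background_phase <- function(ds, static, p = preprocess_params()) {
  d <- dim(ds$velocity)
  idx_static <- which(static)
  des_proto <- poly_design(matrix(0, 1, 3), p$poly_order)
  ncoef <- ncol(des_proto$X)
  if (length(idx_static) < 10 * ncoef) {
    af_stop("correct_background_phase: insufficient static tissue (",
            length(idx_static), " voxels for ", ncoef, " coefficients)")
  }
  ai <- arrayInd(idx_static, d[1:3]) - 1L
  coords <- voxel_to_physical(ai, ds$header)
  des <- poly_design(coords, p$poly_order)
  qrX <- qr(des$X)
  if (qrX$rank < ncoef) {
    af_stop("correct_background_phase: ill-conditioned fit (static voxels ",
            "do not span the polynomial space)")
  }
  # fitted field evaluated on the full grid
  all_ai <- arrayInd(seq_len(prod(d[1:3])), d[1:3]) - 1L
  all_coords <- voxel_to_physical(all_ai, ds$header)
  all_des <- poly_design(all_coords, p$poly_order)
  coefs <- matrix(0, ncoef, 3,
                  dimnames = list(colnames(des$X), c("vx", "vy", "vz")))
  v <- ds$velocity
  for (k in 1:3) {
    acc <- v[, , , 1, k]
    for (tt in 2:d[4]) acc <- acc + v[, , , tt, k]
    tavg <- acc / d[4]
    beta <- qr.coef(qrX, tavg[idx_static])
    beta[is.na(beta)] <- 0
    coefs[, k] <- beta
    fitted3 <- array(all_des$X %*% beta, d[1:3])
    for (tt in seq_len(d[4])) v[, , , tt, k] <- v[, , , tt, k] - fitted3
  }
  ds$velocity <- v
  report <- structure(
    list(poly_coefficients = coefs, exponents = des$exponents,
         n_static_voxels = length(idx_static), params = unclass(p)),
    class = "correction_report"
  )
  list(ds = ds, report = report)
}

#' Fixed-iteration temporal velocity anti-aliasing
#'
#' For a fixed number of passes and each component independently, every
#' voxel-timeframe sample whose difference to its temporal predecessor
#' exceeds VENC is shifted by the multiple of 2*VENC that minimizes the
#' difference (the first frame anchors the sequence and is assumed
#' unwrapped). The operation is idempotent once no sample changes; samples
#' whose temporal differences never exceed VENC are never altered.
#'
#' @param ds a [flow_dataset()].
#' @param p a [preprocess_params()].
#' @return A list: `ds` (unwrapped dataset) and `report` (a
#'   `correction_report` with `n_unwrapped_voxels`, the per-pass correction
#'   counts).
#' @export
unwrap_aliasing <- function(ds, p = preprocess_params()) {
  d <- dim(ds$velocity)
  venc <- venc_ms(ds$header)
  nvox <- prod(d[1:3])
  counts <- integer(p$alias_iterations)
  v <- ds$velocity
  for (k in 1:3) {
    m <- matrix(v[, , , , k], nvox, d[4])
    n_comp <- 0L
    for (pass in seq_len(p$alias_iterations)) {
      n_pass <- 0L
      for (tt in 2:d[4]) {
        dif <- m[, tt] - m[, tt - 1]
        kk <- round(dif / (2 * venc))
        sel <- abs(dif) > venc & kk != 0
        if (any(sel)) {
          m[sel, tt] <- m[sel, tt] - 2 * venc * kk[sel]
          n_pass <- n_pass + sum(sel)
        }
      }
      counts[pass] <- counts[pass] + n_pass
      n_comp <- n_comp + n_pass
      if (n_pass == 0L) break
    }
    if (n_comp > 0L) v[, , , , k] <- array(m, d[1:4])
  }
  ds$velocity <- v
  report <- structure(
    list(n_unwrapped_voxels = counts, params = unclass(p)),
    class = "correction_report"
  )
  list(ds = ds, report = report)
}

#' @export
print.correction_report <- function(x, ...) {
  cat("<correction_report>\n")
  if (!is.null(x$n_static_voxels)) {
    cat("  static voxels:", x$n_static_voxels, "\n")
    cat("  coefficients:\n")
    print(round(x$poly_coefficients, 8))
  }
  if (!is.null(x$n_unwrapped_voxels)) {
    cat("  unwrap corrections per pass:",
        paste(x$n_unwrapped_voxels, collapse = ", "), "\n")
  }
  invisible(x)
}
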