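# Shared fixtures. Heavy phantoms are generated once per session and
# cached; small variants keep unit tests fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# compact U-tube phantom parameters for unit tests
small_phantom_params <- function(...) {
  defaults <- list(
    grid_shape = c(40, 24, 40), voxel_size = c(2, 2, 2),
    n_timeframes = 12, temporal_resolution = 40,
    limb_length = 24, bend_radius = 14, lumen_radius = 6,
    shell_thickness = 4, v_peak = 1.3, pwv_true = 6.4, venc = 150,
    noise_sd = 0
  )
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

small_phantom <- function() cached("small", generate_phantom(small_phantom_params()))

# full-size default phantoms (the study conditions)
default_phantom <- function() cached("default", generate_phantom(phantom_params()))
default_phantom_clean <- function() {
  cached("default_clean", generate_phantom(phantom_params(noise_sd = 0)))
}

# a clean dataset with uniform axial velocity inside a square prism
square_duct_dataset <- function(side_mm = 20, v = 1, voxel = 1, n_t = 1) {
  n_xy <- as.integer(side_mm / voxel + 8)
  nz <- 24L
  d <- c(n_xy, n_xy, nz)
  origin <- -(d * voxel) / 2 + voxel / 2
  h <- scan_header(voxel_size = rep(voxel, 3), temporal_resolution = 40,
                   origin = origin, venc = 200, n_timeframes = n_t)
  xs <- origin[1] + (seq_len(d[1]) - 1) * voxel
  inside1 <- xs > -side_mm / 2 & xs < side_mm / 2
  lumen <- array(FALSE, d)
  lumen[inside1, inside1, ] <- TRUE
  mag <- array(0.02, c(d, n_t))
  vel <- array(0, c(d, n_t, 3))
  for (tt in seq_len(n_t)) {
    mag[, , , tt] <- 0.02 + 0.98 * lumen
    vz <- array(0, d); vz[lumen] <- v
    vel[, , , tt, 3] <- vz
  }
  list(ds = flow_dataset(mag, vel, h), seg = segmentation_mask(lumen),
       area_mm2 = sum(inside1)^2 * voxel^2)
}

# analysis plane constructed directly (unit normal)
make_plane <- function(center, normal, arc = 0) {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(center = center, normal = normal, arc_position = arc),
            class = "analysis_plane")
}

# analytic half-sine flow curves, time-shifted by arc / pwv (+ jitter)
synthetic_curves <- function(arc_positions, pwv, dt = 40, n_t = 20,
                             q_peak = 100, jitter_ms = 0) {
  times <- (seq_len(n_t) - 1) * dt
  cycle <- n_t * dt
  t_sys <- cycle / 3
  lapply(seq_along(arc_positions), function(i) {
    delay <- arc_positions[i] / pwv +
      (if (length(jitter_ms) > 1) jitter_ms[i] else jitter_ms)
    tau <- times - delay
    w <- sin(pi * tau / t_sys)
    w[tau < 0 | tau > t_sys] <- 0
    flow_curve(arc_positions[i], times, q_peak * w)
  })
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
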