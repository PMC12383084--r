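# Synthetic 4D flow phantom: a U-shaped tube (ascending limb, half-torus
# arch, descending limb) with quasi-steady Poiseuille flow whose waveform
# propagates along the centerline at a prescribed pulse wave velocity.
# Every downstream quantity (mask, regions, centerline, flow curves, peak
# velocity, kinetic energy, energy-loss rate, wrapped-voxel set, injected
# background offsets) is known analytically or by construction.

#' Phantom generation parameters
#'
#' Defaults emulate a typical adult thoracic-aorta 4D flow acquisition:
#' 2 mm isotropic voxels, 40 ms temporal resolution, 20 timeframes
#' (800 ms cycle), VENC 150 cm/s, systolic peak velocity 1.3 m/s and a
#' ground-truth pulse wave velocity of 6.4 m/s. The U-tube (60 mm limbs,
#' 30 mm bend radius, 8 mm lumen radius) yields a centerline of about
#' 214 mm, comparable to a thoracic aorta.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param voxel_size numeric length-3 voxel size, mm.
#' @param n_timeframes number of cardiac timeframes.
#' @param temporal_resolution frame spacing, ms.
#' @param limb_length,bend_radius,lumen_radius U-tube geometry, mm.
#' @param v_peak systolic centerline peak velocity, m/s.
#' @param pwv_true imposed pulse wave velocity, m/s.
#' @param venc velocity-encoding limit, cm/s.
#' @param noise_sd Gaussian velocity noise SD, m/s (0.02 by default —
#'   a realistic measurement-noise floor at this VENC; set 0 for
#'   noise-free analytic checks).
#' @param background_poly optional injected background phase offset: a list
#'   with `order` and `coef`, a (n_monomials x 3) matrix of coefficients in
#'   m/s per mm^degree for the monomial basis of [poly_design] coordinates
#'   (physical mm), one column per velocity component.
#' @param alias_fraction fraction of detectable systolic lumen
#'   voxel-samples whose dominant velocity component is wrapped by
#'   -2*VENC*sign(v), emulating phase aliasing; the wrapped set is recorded
#'   in the truth.
#' @param seed RNG seed for noise and wrap selection.
#' @param shell_thickness static-tissue shell thickness around the lumen, mm.
#' @param magnitude_lumen,magnitude_shell,magnitude_background magnitude
#'   levels (arbitrary units).
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64, 64, 64),
                           voxel_size = c(2, 2, 2),
                           n_timeframes = 20,
                           temporal_resolution = 40,
                           limb_length = 60, bend_radius = 30, lumen_radius = 8,
                           v_peak = 1.3, pwv_true = 6.4, venc = 150,
                           noise_sd = 0.02, background_poly = NULL,
                           alias_fraction = 0, seed = 1,
                           shell_thickness = 6,
                           magnitude_lumen = 1, magnitude_shell = 0.3,
                           magnitude_background = 0.02) {
  p <- as.list(environment())
  class(p) <- "phantom_params"
  stopifnot(p$v_peak > 0, p$pwv_true > 0, p$lumen_radius > 0,
            p$alias_fraction >= 0, p$alias_fraction <= 1)
  p
}

# Temporal waveform: half-sine systole over the first third of the cycle.
phantom_waveform <- function(t_ms, cycle_ms) {
  t_sys <- cycle_ms / 3
  w <- sin(pi * t_ms / t_sys)
  w[t_ms < 0 | t_ms > t_sys] <- 0
  w
}

# Analytic U-tube centerline sampled at ~1 mm arc steps.
# Limb 1 (AAo) ascends at x = -Rb, the arch is a half-torus in the x-z
# plane centered at (0, 0, z1), limb 2 (DAo) descends at x = +Rb.
phantom_centerline <- function(p, z_bot, z1, ds = 1) {
  L <- p$limb_length; Rb <- p$bend_radius
  total <- 2 * L + pi * Rb
  s <- seq(0, total, by = ds)
  if (s[length(s)] < total) s <- c(s, total)
  pts <- matrix(0, length(s), 3)
  tans <- matrix(0, length(s), 3)
  i1 <- s <= L
  pts[i1, ] <- cbind(-Rb, 0, z_bot + s[i1])
  tans[i1, ] <- matrix(c(0, 0, 1), sum(i1), 3, byrow = TRUE)
  i2 <- s > L & s <= L + pi * Rb
  th <- pi - (s[i2] - L) / Rb
  pts[i2, ] <- cbind(Rb * cos(th), 0, z1 + Rb * sin(th))
  tans[i2, ] <- cbind(sin(th), 0, -cos(th))
  i3 <- s > L + pi * Rb
  pts[i3, ] <- cbind(Rb, 0, z1 - (s[i3] - L - pi * Rb))
  tans[i3, ] <- matrix(c(0, 0, -1), sum(i3), 3, byrow = TRUE)
  list(s = s, points = pts, tangents = tans, total_length = total)
}

#' Generate a synthetic 4D flow phantom with ground truth
#'
#' Builds a U-shaped tube with a parabolic (quasi-steady Poiseuille) axial
#' velocity profile. The temporal waveform (half-sine systole over the
#' first third of the cycle, zero diastole) is evaluated at
#' `t - s / pwv_true` for centerline arc position `s`, imposing the
#' ground-truth wave speed. A static-tissue shell surrounds the lumen
#' (zero mean velocity), magnitude is high in the lumen, moderate in the
#' shell and low in the background. Optionally adds a polynomial
#' background velocity offset, seeded Gaussian noise, and phase wraps on a
#' recorded set of systolic lumen voxel-samples.
#'
#' @param p a [phantom_params()].
#' @return A list with `ds` (a [flow_dataset()]), `seg` (the ground-truth
#'   [segmentation_mask()] with AAo/arch/DAo labels), and `truth` (a list:
#'   analytic centerline, per-plane flow curves, `vmax_true`, `ke_uJ(t)`,
#'   `el_rate_uW(t)`, `pwv_true`, the wrapped-sample index matrix, injected
#'   offset coefficients, and generator labels for background/shell/lumen).
#' @export
generate_phantom <- function(p = phantom_params()) {
  stopifnot(inherits(p, "phantom_params"))
  d <- p$grid_shape
  vox <- p$voxel_size
  extent <- d * vox
  r_out <- p$lumen_radius + p$shell_thickness
  margin <- 2 * max(vox)
  # vertical placement: bottom caps at z_bot, torus ring center at z1
  z_bot <- -extent[3] / 2 + margin
  z1 <- z_bot + p$limb_length
  if (z1 + p$bend_radius + r_out > extent[3] / 2 - margin ||
      p$bend_radius + r_out > extent[1] / 2 - margin ||
      r_out > extent[2] / 2 - margin) {
    af_stop("generate_phantom: tube geometry exceeds the grid")
  }
  # voxel-0 center at -extent/2: centers then sample the limb axes
  # (x = +/- bend_radius, y = 0) exactly for even grids
  origin <- -extent / 2
  header <- scan_header(
    voxel_size = vox, temporal_resolution = p$temporal_resolution,
    origin = origin, venc = p$venc, n_timeframes = p$n_timeframes
  )

  # physical voxel-center coordinates
  xs <- origin[1] + (seq_len(d[1]) - 1) * vox[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * vox[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * vox[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  L <- p$limb_length; Rb <- p$bend_radius; r <- p$lumen_radius
  in_limbs <- Z <= z1
  # radial distance to / arc position on the nearest limb or the arch ring
  rho <- array(Inf, d); s_arc <- array(NA_real_, d)
  tang <- array(0, c(d, 3))
  limb1 <- in_limbs & X < 0
  rho[limb1] <- sqrt((X[limb1] + Rb)^2 + Y[limb1]^2)
  s_arc[limb1] <- Z[limb1] - z_bot
  t1 <- array(0, d); t1[limb1] <- 1
  limb2 <- in_limbs & X >= 0
  rho[limb2] <- sqrt((X[limb2] - Rb)^2 + Y[limb2]^2)
  s_arc[limb2] <- L + pi * Rb + (z1 - Z[limb2])
  t1[limb2] <- -1
  tang[, , , 3] <- t1
  arch <- !in_limbs
  ring <- sqrt(X[arch]^2 + (Z[arch] - z1)^2)
  rho[arch] <- sqrt((ring - Rb)^2 + Y[arch]^2)
  th <- atan2(Z[arch] - z1, X[arch])        # in (0, pi) above the ring center
  s_arc[arch] <- L + (pi - th) * Rb
  tx <- array(0, d); tz <- array(0, d)
  tx[arch] <- sin(th); tz[arch] <- -cos(th)
  tang[, , , 1] <- tang[, , , 1] + tx
  tang[, , , 3] <- tang[, , , 3] + tz
  below <- Z < z_bot                         # below the open limb ends
  lumen <- rho <= r & !below
  shell <- rho <= r_out & !lumen & !below
  s_arc[below] <- NA_real_

  # magnitude
  magnitude <- array(p$magnitude_background, c(d, p$n_timeframes))
  profile3 <- array(0, d)
  profile3[lumen] <- 1 - (rho[lumen] / r)^2
  for (tt in seq_len(p$n_timeframes)) {
    m3 <- array(p$magnitude_background, d)
    m3[shell] <- p$magnitude_shell
    m3[lumen] <- p$magnitude_lumen
    magnitude[, , , tt] <- m3
  }

  # velocity: v = tangent * v_peak * (1 - rho^2/r^2) * w(t - s/pwv)
  cycle <- p$n_timeframes * p$temporal_resolution
  velocity <- array(0, c(d, p$n_timeframes, 3))
  lum_idx <- which(lumen)
  delay <- s_arc[lum_idx] / p$pwv_true          # mm / (mm/ms) = ms
  prof <- profile3[lum_idx] * p$v_peak
  tan_l <- cbind(tang[, , , 1][lum_idx], tang[, , , 2][lum_idx], tang[, , , 3][lum_idx])
  frame_w <- matrix(0, length(lum_idx), p$n_timeframes)
  for (tt in seq_len(p$n_timeframes)) {
    t_ms <- (tt - 1) * p$temporal_resolution
    w <- phantom_waveform(t_ms - delay, cycle)
    frame_w[, tt] <- w
    for (k in 1:3) {
      sl <- array(0, d)
      sl[lum_idx] <- prof * w * tan_l[, k]
      velocity[, , , tt, k] <- sl
    }
  }

  truth <- list(pwv_true = p$pwv_true, vmax_true = p$v_peak,
                lumen = lumen, shell = shell,
                background = !lumen & !shell,
                arc_position = s_arc, params = p)

  # injected background polynomial offset (added everywhere)
  if (!is.null(p$background_poly)) {
    bp <- p$background_poly
    coords <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
    des <- poly_design(coords, bp$order)
    for (k in 1:3) {
      off3 <- array(des$X %*% bp$coef[, k], d)
      for (tt in seq_len(p$n_timeframes)) {
        velocity[, , , tt, k] <- velocity[, , , tt, k] + off3
      }
    }
    truth$offset_coefficients <- bp$coef
    truth$offset_order <- bp$order
  }

  # seeded Gaussian noise on velocity (and light magnitude jitter)
  with_seed(p$seed, {
    if (p$noise_sd > 0) {
      velocity <- velocity + array(rnorm(length(velocity), sd = p$noise_sd),
                                   dim(velocity))
      magnitude <- magnitude +
        array(abs(rnorm(length(magnitude), sd = 0.01 * p$magnitude_lumen)),
              dim(magnitude))
    }
    # wrap a fraction of detectable systolic lumen voxel-samples
    wrapped <- matrix(integer(0), 0, 3,
                      dimnames = list(NULL, c("voxel", "frame", "component")))
    if (p$alias_fraction > 0) {
      detectable <- frame_w > 0.3 & col(frame_w) > 1 &
        matrix(prof > 0.05 * p$v_peak, nrow(frame_w), ncol(frame_w))
      cand <- which(detectable, arr.ind = TRUE)
      n_wrap <- floor(p$alias_fraction * nrow(cand))
      if (n_wrap > 0) {
        pick <- cand[sample.int(nrow(cand), n_wrap), , drop = FALSE]
        wraps <- matrix(0L, n_wrap, 3)
        for (q in seq_len(n_wrap)) {
          vi <- lum_idx[pick[q, 1]]; tt <- pick[q, 2]
          comp <- which.max(abs(tan_l[pick[q, 1], ]))
          ai <- arrayInd(vi, d)
          v0 <- velocity[ai[1], ai[2], ai[3], tt, comp]
          velocity[ai[1], ai[2], ai[3], tt, comp] <-
            v0 - 2 * venc_ms(header) * sign(v0)
          wraps[q, ] <- c(vi, tt, comp)
        }
        wrapped <- wraps
        colnames(wrapped) <- c("voxel", "frame", "component")
      }
    }
    truth$wrapped_samples <- wrapped
  })

  ds <- flow_dataset(magnitude, velocity, header)

  # ground-truth segmentation with region labels:
  # limb 1 -> AAo, arch -> arch, limb 2 -> DAo
  regions <- array(0L, d)
  regions[lumen & limb1] <- region_codes()[["AAo"]]
  regions[lumen & arch] <- region_codes()[["arch"]]
  regions[lumen & limb2] <- region_codes()[["DAo"]]
  seg <- segmentation_mask(lumen, regions)

  # analytic centerline and per-plane flow curves (time-shifted copies)
  cl_true <- phantom_centerline(p, z_bot, z1)
  times <- (seq_len(p$n_timeframes) - 1) * p$temporal_resolution
  plane_s <- seq(0, cl_true$total_length, by = 25)
  curves <- lapply(plane_s, function(ss) {
    q <- p$v_peak / 2 * pi * r^2 * phantom_waveform(times - ss / p$pwv_true, cycle)
    flow_curve(arc_position = ss, times = times, q = q)
  })
  truth$centerline <- cl_true
  truth$flow_curves <- curves
  truth$region_boundaries_mm <- c(AAo_arch = L, arch_DAo = L + pi * Rb)

  # analytic energetics of the noise-free field (cycle-resolved):
  # KE(t) = 0.5 rho (pi r^2 / 3) v_peak^2 Int w(t - s/pwv)^2 ds
  # EL_rate(t) = 2 pi mu v_peak^2 Int w(t - s/pwv)^2 ds
  const <- hemo_constants()
  sgrid <- cl_true$s
  dsg <- c(diff(sgrid), 0)
  w2 <- vapply(times, function(t_ms) {
    sum(phantom_waveform(t_ms - sgrid / p$pwv_true, cycle)^2 * dsg)
  }, numeric(1))                               # mm
  truth$ke_uJ <- 0.5 * const$rho * (pi * r^2 / 3) * p$v_peak^2 * w2 * 1e-9 * 1e6
  truth$el_rate_uW <- 2 * pi * const$mu * p$v_peak^2 * w2 * 1e-3 * 1e6

  list(ds = ds, seg = seg, truth = truth)
}

#' Steady Poiseuille cylinder dataset with analytic energetics
#'
#' A straight rigid tube along z with a steady parabolic velocity profile
#' `v_z(rho) = v_max (1 - rho^2/R^2)`, for validating the kinetic-energy
#' and viscous-energy-loss integrals against their closed forms
#' KE = pi rho v_max^2 R^2 L / 6 and EL_rate = 2 pi mu v_max^2 L.
#'
#' @param radius lumen radius, mm.
#' @param length tube length, mm.
#' @param v_max centerline velocity, m/s.
#' @param voxel_size isotropic voxel edge, mm.
#' @param n_timeframes frames (steady flow repeated).
#' @param venc VENC, cm/s.
#' @param margin background margin, voxels.
#' @return A list: `ds`, `seg`, and `truth` with the analytic `ke_uJ` and
#'   `el_rate_uW`.
#' @export
poiseuille_cylinder <- function(radius = 8, length = 60, v_max = 1,
                                voxel_size = 1, n_timeframes = 1,
                                venc = 200, margin = 3) {
  nr <- ceiling(2 * (radius + margin * voxel_size) / voxel_size)
  nz <- ceiling(length / voxel_size) + 2 * margin
  d <- c(nr, nr, nz)
  vox <- rep(voxel_size, 3)
  origin <- -(d * vox) / 2 + vox / 2
  header <- scan_header(voxel_size = vox, temporal_resolution = 40,
                        origin = origin, venc = venc,
                        n_timeframes = n_timeframes)
  xs <- origin[1] + (seq_len(d[1]) - 1) * vox[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * vox[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * vox[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  rho2 <- X^2 + Y^2
  z0 <- -length / 2; z1 <- length / 2
  lumen <- rho2 <= radius^2 & Z >= z0 & Z <= z1
  vz <- array(0, d)
  vz[lumen] <- v_max * (1 - rho2[lumen] / radius^2)
  magnitude <- array(0.02, c(d, n_timeframes))
  velocity <- array(0, c(d, n_timeframes, 3))
  for (tt in seq_len(n_timeframes)) {
    magnitude[, , , tt] <- 0.02 + 0.98 * lumen
    velocity[, , , tt, 3] <- vz
  }
  const <- hemo_constants()
  truth <- list(
    ke_uJ = pi * const$rho * v_max^2 * radius^2 * length / 6 * 1e-9 * 1e6,
    el_rate_uW = 2 * pi * const$mu * v_max^2 * length * 1e-3 * 1e6,
    v_max = v_max, radius = radius, length = length
  )
  list(ds = flow_dataset(magnitude, velocity, header),
       seg = segmentation_mask(lumen), truth = truth)
}
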