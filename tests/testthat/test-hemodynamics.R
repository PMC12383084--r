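# Peak velocity filtering, kinetic energy, viscous energy loss, and
# pulse wave velocity.

# independent brute-force implementation of the spike filter used as oracle
oracle_filter <- function(speeds) {
  n <- length(speeds)
  srt <- sort(speeds)
  n_top <- max(10, ceiling(0.01 * n))
  top <- srt[(n - n_top + 1):n]
  gaps <- diff(top)
  thr <- 10 * mean(gaps)
  keep <- top[1]
  for (i in seq_along(gaps)) {
    if (gaps[i] > thr && thr > 0) break
    keep <- top[i + 1]
  }
  keep
}

make_speed_dataset <- function(speeds) {
  n <- length(speeds)
  nx <- ceiling(n^(1 / 3)) + 1
  d <- c(nx, nx, nx)
  vel <- array(0, c(d, 1, 3))
  vz <- numeric(prod(d)); vz[seq_len(n)] <- speeds
  vel[, , , 1, 3] <- array(vz, d)
  region <- array(FALSE, d); region[seq_len(n)] <- TRUE
  h <- scan_header(c(1, 1, 1), 40, 100 * (max(speeds) + 1), 1)
  list(ds = flow_dataset(array(1, c(d, 1)), vel, h), region = region)
}

test_that("peak-velocity spike filter matches the worked example", {
  speeds <- c(seq(0.1, 1.8, length.out = 9900),
              seq(1.900, 1.998, by = 0.001), 3.0)
  sd <- make_speed_dataset(speeds)
  got <- peak_velocity(sd$ds, sd$region)
  expect_equal(got$vmax, 1.998, tolerance = 1e-12)
  expect_identical(got$n_removed, 1L)
})

test_that("peak-velocity filter equals a brute-force oracle on random sets", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(50:2000, 1)
    speeds <- abs(rnorm(n, 1, 0.4))
    if (rep %% 3 == 0) speeds <- c(speeds, max(speeds) + runif(1, 0.5, 3))
    sd <- make_speed_dataset(speeds)
    got <- peak_velocity(sd$ds, sd$region)
    expect_equal(got$vmax, oracle_filter(speeds), tolerance = 1e-12)
  }
})

test_that("peak-velocity filter leaves uniform and evenly spaced data alone", {
  sd <- make_speed_dataset(rep(1.2, 500))
  got <- peak_velocity(sd$ds, sd$region)
  expect_equal(got$vmax, 1.2)
  expect_identical(got$n_removed, 0L)
  sd2 <- make_speed_dataset(seq(0.5, 2.0, length.out = 400))
  got2 <- peak_velocity(sd2$ds, sd2$region)
  expect_equal(got2$vmax, 2.0)
  expect_identical(got2$n_removed, 0L)
  # tiny regions fall back to the plain maximum with a warning
  sd3 <- make_speed_dataset(c(0.5, 3.0))
  expect_warning(got3 <- peak_velocity(sd3$ds, sd3$region), "plain maximum")
  expect_equal(got3$vmax, 3.0)
})

test_that("kinetic energy matches closed forms", {
  # single voxel, dV = 1 mm^3, |v| = 1 m/s, rho = 1060 -> 0.53 uJ
  h <- scan_header(c(1, 1, 1), 40, 200, 1)
  vel <- array(0, c(3, 3, 3, 1, 3)); vel[2, 2, 2, 1, 1] <- 1
  ds <- flow_dataset(array(1, c(3, 3, 3, 1)), vel, h)
  region <- array(FALSE, c(3, 3, 3)); region[2, 2, 2] <- TRUE
  ke <- kinetic_energy(ds, region)
  expect_equal(ke$ke_total_peak_uJ, 0.53, tolerance = 1e-12)
  # uniform speed v in volume V: KE = 0.5 rho V v^2 exactly
  vel2 <- array(0, c(4, 4, 4, 1, 3)); vel2[, , , 1, 2] <- 0.8
  ds2 <- flow_dataset(array(1, c(4, 4, 4, 1)), vel2,
                      scan_header(c(2, 2, 2), 40, 200, 1))
  all_reg <- array(TRUE, c(4, 4, 4))
  expect_equal(kinetic_energy(ds2, all_reg)$ke_total_peak_uJ,
               0.5 * 1060 * (64 * 8 * 1e-9) * 0.8^2 * 1e6, tolerance = 1e-12)
  # Poiseuille cylinder: KE = pi rho vmax^2 R^2 L / 6 within 2%
  cy <- poiseuille_cylinder()
  got <- kinetic_energy(cy$ds, cy$seg$whole)
  expect_equal(got$ke_total_peak_uJ, cy$truth$ke_uJ, tolerance = 0.02)
})

test_that("viscous energy loss matches closed forms and symmetries", {
  h <- scan_header(c(1, 1, 1), 40, 200, 1)
  # uniform velocity: zero gradients, zero dissipation
  vel <- array(0, c(6, 6, 6, 1, 3)); vel[, , , 1, 3] <- 0.7
  ds <- flow_dataset(array(1, c(6, 6, 6, 1)), vel, h)
  expect_identical(viscous_energy_loss(ds, array(TRUE, c(6, 6, 6)))$el_rate_peak_uW, 0)
  # rigid rotation v = (-wy, wx, 0): antisymmetric gradient, Phi = 0
  xs <- (0:5) - 2.5
  vel2 <- array(0, c(6, 6, 6, 1, 3))
  for (i in 1:6) for (j in 1:6) {
    vel2[i, j, , 1, 1] <- -0.05 * xs[j]
    vel2[i, j, , 1, 2] <- 0.05 * xs[i]
  }
  ds2 <- flow_dataset(array(1, c(6, 6, 6, 1)), vel2, h)
  expect_lt(viscous_energy_loss(ds2, array(TRUE, c(6, 6, 6)))$el_rate_peak_uW, 1e-9)
  # Poiseuille cylinder: EL_rate = 2 pi mu vmax^2 L within 10%
  cy <- poiseuille_cylinder()
  got <- viscous_energy_loss(cy$ds, cy$seg$whole)
  expect_equal(got$el_rate_peak_uW, cy$truth$el_rate_uW, tolerance = 0.10)
  # single-voxel region is rejected
  one <- array(FALSE, c(6, 6, 6)); one[3, 3, 3] <- TRUE
  expect_error(viscous_energy_loss(ds, one), "gradient undefined")
})

test_that("KE and EL scale quadratically and Vmax linearly with velocity", {
  ph <- small_phantom()
  region <- ph$truth$lumen
  ke1 <- kinetic_energy(ph$ds, region)$ke_total_peak_uJ
  el1 <- viscous_energy_loss(ph$ds, region)$el_rate_peak_uW
  v1 <- peak_velocity(ph$ds, region)$vmax
  ds2 <- ph$ds
  ds2$velocity <- 2 * ds2$velocity
  expect_equal(kinetic_energy(ds2, region)$ke_total_peak_uJ, 4 * ke1,
               tolerance = 1e-9)
  expect_equal(viscous_energy_loss(ds2, region)$el_rate_peak_uW, 4 * el1,
               tolerance = 1e-9)
  expect_equal(peak_velocity(ds2, region)$vmax, 2 * v1, tolerance = 1e-9)
})

test_that("KE and EL are invariant under 90-degree frame rotations", {
  ph <- small_phantom()
  region <- ph$truth$lumen
  ke1 <- kinetic_energy(ph$ds, region)$ke_total_uJ
  el1 <- viscous_energy_loss(ph$ds, region)$el_rate_uW
  # rotate grid and velocity vectors by +90 degrees about z:
  # positions (x,y,z) -> (-y,x,z), vectors v -> (-vy,vx,vz)
  rot_arr <- function(a) {
    b <- aperm(a, c(2, 1, 3))
    b[rev(seq_len(dim(b)[1])), , , drop = FALSE]
  }
  d <- dim(ph$ds$magnitude)
  d2 <- c(d[2], d[1], d[3], d[4])
  mag2 <- array(0, d2)
  vel2 <- array(0, c(d2, 3))
  for (tt in seq_len(d[4])) {
    mag2[, , , tt] <- rot_arr(ph$ds$magnitude[, , , tt])
    vx <- rot_arr(ph$ds$velocity[, , , tt, 1])
    vy <- rot_arr(ph$ds$velocity[, , , tt, 2])
    vz <- rot_arr(ph$ds$velocity[, , , tt, 3])
    vel2[, , , tt, 1] <- -vy
    vel2[, , , tt, 2] <- vx
    vel2[, , , tt, 3] <- vz
  }
  h2 <- scan_header(ph$ds$header$voxel_size[c(2, 1, 3)],
                    ph$ds$header$temporal_resolution, ph$ds$header$venc,
                    ph$ds$header$n_timeframes)
  ds2 <- flow_dataset(mag2, vel2, h2)
  region2 <- rot_arr(region)
  expect_equal(kinetic_energy(ds2, region2)$ke_total_uJ, ke1, tolerance = 1e-9)
  expect_equal(viscous_energy_loss(ds2, region2)$el_rate_uW, el1, tolerance = 1e-6)
})

test_that("PWV is recovered from exact time-shifted flow curves", {
  for (pv in c(3, 6.4, 10)) {
    curves <- synthetic_curves(seq(0, 200, by = 25), pwv = pv)
    got <- pulse_wave_velocity(curves)
    expect_true(got$reliable)
    expect_lt(abs(got$pwv - pv) / pv, 0.05)
  }
})

test_that("PWV flags identical curves as unreliable", {
  curves <- synthetic_curves(seq(0, 200, by = 25), pwv = 1e12)  # no delay
  got <- pulse_wave_velocity(curves)
  expect_false(got$reliable)
  expect_true(is.na(got$pwv))
  expect_identical(got$flag, "unreliable PWV")
  expect_length(got$delays, 9)
  expect_error(pulse_wave_velocity(curves[1:2]), "at least 3")
})

test_that("PWV tolerates per-plane delay jitter", {
  set.seed(5)
  arc <- seq(0, 225, by = 25)  # 10 planes
  jit <- runif(length(arc), -1, 1)
  jit[1] <- 0
  curves <- synthetic_curves(arc, pwv = 6.4, jitter_ms = jit)
  got <- pulse_wave_velocity(curves)
  expect_lt(abs(got$pwv - 6.4) / 6.4, 0.10)
})

test_that("tidy/glance/autoplot summarize a PWV fit", {
  curves <- synthetic_curves(seq(0, 200, by = 25), pwv = 6.4)
  got <- pulse_wave_velocity(curves)
  td <- generics::tidy(got)
  expect_identical(nrow(td), 9L)
  gl <- generics::glance(got)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$reliable)
  p <- ggplot2::autoplot(got)
  expect_s3_class(p, "ggplot")
})
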