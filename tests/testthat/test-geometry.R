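# PC-MRA, segmentation handling, centerline, analysis planes, flow
# curves, and the AAo/arch/DAo region split.

test_that("PC-MRA is magnitude x speed averaged over time", {
  h <- scan_header(c(1, 1, 1), 40, 200, 2)
  mag <- array(2, c(4, 4, 4, 2))
  vel <- array(0, c(4, 4, 4, 2, 3))
  ds0 <- flow_dataset(mag, vel, h)
  expect_identical(max(compute_pcmra(ds0)), 0)
  vel[, , , , 1] <- 0.3; vel[, , , , 2] <- 0.4
  ds1 <- flow_dataset(mag, vel, h)
  expect_equal(compute_pcmra(ds1), array(2 * 0.5, c(4, 4, 4)), tolerance = 1e-12)
})

test_that("PC-MRA improves lumen-to-background contrast over magnitude", {
  ph <- default_phantom()
  pc <- compute_pcmra(ph$ds)
  mag <- apply(ph$ds$magnitude, c(1, 2, 3), mean)
  contrast <- function(img) {
    mean(img[ph$truth$lumen]) / mean(img[ph$truth$background])
  }
  expect_gt(contrast(pc), contrast(mag))
})

test_that("threshold segmentation recovers the phantom lumen", {
  ph <- default_phantom()
  pc <- compute_pcmra(ph$ds)
  seg <- threshold_segment(pc, ph$ds, fraction = 0.2)
  expect_gte(dice_coef(seg$whole, ph$seg$whole), 0.9)
  # fraction 1 keeps only the argmax voxel; fraction 0 the whole support
  expect_identical(sum(threshold_segment(pc, ph$ds, fraction = 1)$whole), 1L)
  full <- threshold_segment(pc, ph$ds, fraction = 0)
  expect_identical(dim(full$whole), dim(pc))
})

test_that("external masks are grid-checked and reduced to one component", {
  ph <- small_phantom()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  m <- ph$seg$whole
  blob <- m
  blob[2, 2, 2] <- TRUE  # detached 1-voxel blob in a corner
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(blob), dim(blob))), f)
  seg <- load_segmentation(f, ph$ds)
  expect_identical(seg$whole, m)
  expect_match(attr(seg, "qc_flags"), "disconnected")
  # grid mismatch and dimensionality errors
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1L, c(4, 4, 4))), f2)
  expect_error(load_segmentation(f2, ph$ds), "does not match")
  f3 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1L, 4, 4)), f3)
  expect_error(load_segmentation(f3, ph$ds), "3D")
})

test_that("centerline of a straight cylinder lies on the axis", {
  cy <- poiseuille_cylinder(radius = 8, length = 120, voxel_size = 2,
                            n_timeframes = 1)
  cl <- extract_centerline(cy$seg, cy$ds$header)
  expect_lt(abs(max(cl$arc_length) - 120), 2 * 2)      # within 2 voxels
  expect_lt(max(sqrt(cl$points[, 1]^2 + cl$points[, 2]^2)), 2)  # <= 1 voxel
  expect_true(all(abs(sqrt(rowSums(cl$tangents^2)) - 1) < 1e-6))
  expect_true(all(diff(cl$arc_length) > 0))
})

test_that("U-tube centerline length matches 2L + pi R_b", {
  ph <- default_phantom()
  cl <- extract_centerline(ph$seg, ph$ds$header)
  expect_lt(abs(max(cl$arc_length) - ph$truth$centerline$total_length) /
              ph$truth$centerline$total_length, 0.05)
  # oriented ascending-limb first: start tangent points superiorly and the
  # start sits on the anterior (negative-x) limb
  expect_gt(cl$tangents[1, 3], 0.5)
  expect_lt(cl$points[1, 1], 0)
})

test_that("centerline extraction rejects degenerate masks", {
  h <- scan_header(c(1, 1, 1), 40, 150, 1)
  empty <- segmentation_mask(array(FALSE, c(8, 8, 8)))
  expect_error(extract_centerline(empty, h), "empty mask")
  tiny <- array(FALSE, c(8, 8, 8)); tiny[4:5, 4:5, 4:5] <- TRUE
  expect_error(extract_centerline(segmentation_mask(tiny), h), "too small")
})

test_that("centerline length is invariant under 90-degree rotations", {
  cy <- poiseuille_cylinder(radius = 6, length = 60, voxel_size = 2,
                            n_timeframes = 1)
  cl_z <- extract_centerline(cy$seg, cy$ds$header)
  # rotate mask so the axis runs along x
  mask_x <- aperm(cy$seg$whole, c(3, 2, 1))
  d <- dim(mask_x)
  h <- scan_header(c(2, 2, 2), 40, 200, n_timeframes = 1,
                   origin = -(d * 2) / 2 + 1)
  cl_x <- extract_centerline(segmentation_mask(mask_x), h)
  expect_lt(abs(max(cl_x$arc_length) - max(cl_z$arc_length)), 2)
})

test_that("plane placement follows floor(length/spacing) + 1", {
  mk_cl <- function(L) {
    s <- seq(0, L, by = 1)
    centerline(cbind(0, 0, s), s, matrix(rep(c(0, 0, 1), length(s)),
                                         ncol = 3, byrow = TRUE))
  }
  expect_length(place_planes(mk_cl(130), 25), 6)
  pos <- vapply(place_planes(mk_cl(130), 25), function(p) p$arc_position, numeric(1))
  expect_equal(pos, c(0, 25, 50, 75, 100, 125))
  expect_length(place_planes(mk_cl(24), 25), 1)
  for (L in c(37, 99, 200)) {
    expect_length(place_planes(mk_cl(L), 25), floor(L / 25) + 1)
  }
})

test_that("through-plane flow integrates v . n dA in mL/s", {
  # uniform 1 m/s axial velocity through a 400 mm^2 square duct
  duct <- square_duct_dataset(side_mm = 20, v = 1, voxel = 1)
  pl <- make_plane(c(0, 0, 0), c(0, 0, 1))
  q <- flow_time_curve(duct$ds, duct$seg, pl)
  # a uniform (plug) profile is worst-case for wall partial volume: edge
  # samples interpolate against the zero-velocity background
  expect_equal(q$q[1], 400, tolerance = 0.05)
  # zero velocity gives an identically zero curve
  z <- duct$ds; z$velocity[] <- 0
  expect_identical(max(abs(flow_time_curve(z, duct$seg, pl)$q)), 0)
  # Poiseuille: Q = vmax A / 2
  cy <- poiseuille_cylinder(radius = 8, length = 40, v_max = 1, voxel_size = 1)
  qp <- flow_time_curve(cy$ds, cy$seg, make_plane(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(qp$q[1], 1 * pi * 8^2 / 2, tolerance = 0.02)
  # a plane far outside the vessel errors
  expect_error(flow_time_curve(cy$ds, cy$seg, make_plane(c(0, 0, 500), c(0, 0, 1))),
               "plane misses vessel")
})

test_that("steady flow is conserved along the vessel at interior planes", {
  cy <- poiseuille_cylinder(radius = 8, length = 120, voxel_size = 2,
                            n_timeframes = 1)
  cl <- extract_centerline(cy$seg, cy$ds$header)
  planes <- place_planes(cl, 25)
  interior <- Filter(function(p) {
    p$arc_position > 4 && p$arc_position < max(cl$arc_length) - 4
  }, planes)
  qs <- vapply(interior, function(p) flow_time_curve(cy$ds, cy$seg, p)$q[1],
               numeric(1))
  expect_gt(length(qs), 2)
  expect_lt((max(qs) - min(qs)) / mean(qs), 0.05)
})

test_that("aorta region split labels limbs and arch and partitions the mask", {
  ph <- default_phantom_clean()
  cl <- extract_centerline(ph$seg, ph$ds$header)
  seg <- split_aorta_regions(ph$seg, cl, ph$ds$header)
  codes <- region_codes()
  expect_identical(sort(unique(seg$regions[seg$whole])), c(1L, 2L, 3L))
  expect_true(all((seg$regions != 0L) == seg$whole))
  # limb interiors (far from the junctions) carry the correct labels; the
  # +/-0.5 tangent rule moves the nominal boundary R_b * pi/3 into the bend
  L <- ph$truth$params$limb_length
  Rb <- ph$truth$params$bend_radius
  shiftd <- Rb * pi / 3
  s <- ph$truth$arc_position
  deep_aao <- ph$truth$lumen & !is.na(s) & s < L - 5
  deep_arch <- ph$truth$lumen & !is.na(s) & s > L + shiftd + 5 &
    s < L + pi * Rb - shiftd - 5
  deep_dao <- ph$truth$lumen & !is.na(s) & s > L + pi * Rb + 5
  expect_true(all(seg$regions[deep_aao] == codes[["AAo"]]))
  expect_true(all(seg$regions[deep_arch] == codes[["arch"]]))
  expect_true(all(seg$regions[deep_dao] == codes[["DAo"]]))
})

test_that("straight vessels fall back to equal arc-length thirds", {
  cy <- poiseuille_cylinder(radius = 6, length = 90, voxel_size = 2,
                            n_timeframes = 1)
  cl <- extract_centerline(cy$seg, cy$ds$header)
  seg <- split_aorta_regions(cy$seg, cl, cy$ds$header)
  counts <- table(seg$regions[seg$whole])
  expect_length(counts, 3)
  expect_lt(max(counts) / min(counts), 1.3)
})
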