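# Segmentation handling, PC-MRA, centerline extraction, analysis-plane
# placement, through-plane flow-time curves, and the AAo/arch/DAo split.

#' Phase-contrast MR angiogram
#'
#' Time average over frames of magnitude times speed. The PC-MRA
#' suppresses static tissue and highlights the vessel lumen, giving the
#' threshold-based fallback segmentation a higher lumen-to-background
#' contrast than the magnitude alone.
#'
#' @param ds a [flow_dataset()].
#' @return Non-negative numeric array `[X,Y,Z]`.
#' @export
compute_pcmra <- function(ds) {
  d <- dim(ds$magnitude)
  nvox <- prod(d[1:3])
  speed <- sqrt(matrix(ds$velocity[, , , , 1], nvox, d[4])^2 +
                  matrix(ds$velocity[, , , , 2], nvox, d[4])^2 +
                  matrix(ds$velocity[, , , , 3], nvox, d[4])^2)
  pc <- rowMeans(matrix(ds$magnitude, nvox, d[4]) * speed)
  array(pc, d[1:3])
}

#' Load an external aortic segmentation
#'
#' Reads a binary mask from NIfTI (`.nii`/`.nii.gz`) or from the
#' `/segmentation` group of an HDF5 container. The grid must match the
#' dataset exactly (no resampling is performed). Only the largest
#' 26-connected component is retained; if smaller components were
#' discarded a QC flag is raised on the returned mask (attribute
#' `qc_flags`).
#'
#' @param path mask file.
#' @param ds the [flow_dataset()] the mask belongs to.
#' @return A [segmentation_mask()], possibly with a `qc_flags` attribute.
#' @export
load_segmentation <- function(path, ds) {
  if (!file.exists(path)) af_stop("load_segmentation: no such file: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
  } else {
    got <- read_flow_h5(path)
    if (is.null(got$seg)) af_stop("load_segmentation: no segmentation in ", path)
    arr <- got$seg$whole
  }
  if (length(dim(arr)) != 3) {
    af_stop("load_segmentation: mask must be 3D, got ",
            paste(dim(arr), collapse = "x"))
  }
  dsdim <- dim(ds$magnitude)[1:3]
  if (!all(dim(arr) == dsdim)) {
    af_stop("load_segmentation: mask grid ", paste(dim(arr), collapse = "x"),
            " does not match dataset grid ", paste(dsdim, collapse = "x"))
  }
  whole <- array(arr != 0, dim(arr))
  lc <- largest_component(whole, ds$header$voxel_size)
  seg <- segmentation_mask(lc$mask)
  if (lc$n_components > 1) {
    attr(seg, "qc_flags") <- sprintf("segmentation: %d disconnected components discarded",
                                     lc$n_components - 1)
  }
  seg
}

#' Threshold segmentation of the PC-MRA
#'
#' Fallback lumen segmentation: voxels at or above `fraction` times the
#' PC-MRA maximum, restricted to the largest 26-connected component.
#'
#' @param pcmra array from [compute_pcmra()].
#' @param ds the source [flow_dataset()].
#' @param fraction threshold as a fraction of the PC-MRA maximum
#'   (default 0.2).
#' @return A [segmentation_mask()].
#' @export
threshold_segment <- function(pcmra, ds, fraction = 0.2) {
  raw <- pcmra >= fraction * max(pcmra)
  if (!any(raw)) af_stop("threshold_segment: empty segmentation")
  if (sum(raw) == 1) return(segmentation_mask(array(raw, dim(pcmra))))
  lc <- largest_component(array(raw, dim(pcmra)), ds$header$voxel_size)
  segmentation_mask(lc$mask)
}

#' Construct a centerline object
#'
#' @param points N x 3 physical coordinates, mm.
#' @param arc_length strictly increasing N-vector, mm, from 0.
#' @param tangents N x 3 unit tangent vectors.
#' @return An object of class `centerline`.
#' @export
centerline <- function(points, arc_length, tangents) {
  stopifnot(nrow(points) == length(arc_length), nrow(tangents) == nrow(points))
  if (any(diff(arc_length) <= 0)) af_stop("centerline: arc_length must be strictly increasing")
  if (any(abs(sqrt(rowSums(tangents^2)) - 1) > 1e-6)) {
    af_stop("centerline: tangents must be unit vectors")
  }
  structure(list(points = points, arc_length = arc_length, tangents = tangents),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat("<centerline> ", nrow(x$points), " points, length ",
      fmt_num(max(x$arc_length)), " mm\n", sep = "")
  invisible(x)
}

total_length <- function(cl) max(cl$arc_length)

# moving-average smoothing of a polyline (window truncated at the ends)
smooth_polyline <- function(pts, window = 5) {
  n <- nrow(pts)
  hw <- floor(window / 2)
  out <- pts
  for (i in seq_len(n)) {
    lo <- max(1, i - hw); hi <- min(n, i + hw)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}

# resample a polyline to uniform arc-length steps
resample_polyline <- function(pts, step = 1) {
  seglen <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seglen > 1e-12)
  pts <- pts[keep, , drop = FALSE]
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  L <- cum[length(cum)]
  s <- seq(0, L, by = step)
  if (s[length(s)] < L - 1e-9) s <- c(s, L)
  out <- vapply(1:3, function(k) approx(cum, pts[, k], xout = s)$y,
                numeric(length(s)))
  list(points = matrix(out, ncol = 3), arc_length = s)
}

central_diff_tangents <- function(pts) {
  n <- nrow(pts)
  tg <- matrix(0, n, 3)
  tg[1, ] <- pts[2, ] - pts[1, ]
  tg[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  normalize_rows(tg)
}

#' Extract the aortic centerline from a segmentation
#'
#' Computes a medialness-penalized minimal-cost path through the voxel
#' adjacency graph of the mask: edge cost is the physical step length
#' divided by the squared inscribed-sphere radius (chamfer distance
#' transform), so the optimal path hugs the vessel axis. Endpoints are
#' found by a double Dijkstra sweep and re-centered by maximal wall
#' distance; the path is then extended to the vessel openings along the
#' local tangent, smoothed with a moving average (window 5), resampled to
#' 1 mm arc-length steps, and oriented so the ascending aorta comes first
#' (start tangent pointing superiorly; ties broken toward the anterior
#' limb, overridable).
#'
#' @param seg a [segmentation_mask()] (single connected component, at
#'   least 100 voxels).
#' @param header the [scan_header()] providing voxel geometry.
#' @param orientation `"auto"` (superior-pointing start tangent, anterior
#'   tie-break), `"keep"` or `"flip"`.
#' @return A [centerline()].
#' @export
extract_centerline <- function(seg, header, orientation = c("auto", "keep", "flip")) {
  orientation <- match.arg(orientation)
  mask <- seg$whole
  n_vox <- sum(mask)
  if (n_vox == 0) af_stop("extract_centerline: empty mask")
  if (n_vox < 100) {
    af_stop("extract_centerline: mask too small (", n_vox, " voxels, need >= 100)")
  }
  bb <- mask_bbox(mask, pad = 1)
  sub <- mask[bb$x, bb$y, bb$z]
  spacing <- header$voxel_size
  edt <- chamfer_edt(sub, spacing)
  vg <- voxel_graph(sub, spacing)
  edt_v <- edt[vg$lin]
  if (igraph::components(vg$g)$no > 1) {
    af_stop("extract_centerline: mask is not a single connected component")
  }
  eps <- (0.25 * min(spacing))^2
  ends <- igraph::ends(vg$g, igraph::E(vg$g))
  pen <- vg$len / ((edt_v[ends[, 1]]^2 + edt_v[ends[, 2]]^2) / 2 + eps)

  far_centered <- function(from) {
    dd <- as.vector(igraph::distances(vg$g, v = from, weights = vg$len))
    cand <- which(dd >= max(dd) - max(edt_v))
    cand[which.max(edt_v[cand])]
  }
  src <- which.max(edt_v)
  e1 <- far_centered(src)
  e2 <- far_centered(e1)
  e1 <- far_centered(e2)
  vpath <- igraph::shortest_paths(vg$g, from = e1, to = e2, weights = pen)$vpath[[1]]
  path_idx <- as.integer(vpath)
  if (length(path_idx) < 2) af_stop("extract_centerline: no open path through mask")
  # voxel indices in the full grid (0-based) -> physical mm
  ai <- vg$arr_ind[path_idx, , drop = FALSE]
  ai_full <- sweep(ai, 2, bb$lo - 1L, `+`) - 1L
  pts <- voxel_to_physical(ai_full, header)

  # medial recentering: move each path point to the centroid of the mask
  # cross-section in a thin slab perpendicular to the local path direction
  mask_pts <- voxel_to_physical(which(mask, arr.ind = TRUE) - 1L, header)
  r_max <- max(edt_v)
  tg0 <- central_diff_tangents(pts)
  slab_h <- max(header$voxel_size)
  for (i in seq_len(nrow(pts))) {
    rel <- sweep(mask_pts, 2, pts[i, ])
    dn <- rel %*% tg0[i, ]
    inplane2 <- rowSums(rel^2) - dn^2
    sel <- abs(dn) <= slab_h & inplane2 <= (1.5 * r_max)^2
    if (sum(sel) >= 3) {
      cen <- colMeans(mask_pts[sel, , drop = FALSE])
      # keep the along-path coordinate, correct only in-plane
      off <- cen - pts[i, ]
      pts[i, ] <- pts[i, ] + off - sum(off * tg0[i, ]) * tg0[i, ]
    }
  }

  # extend both ends to the vessel openings along the local tangent
  extend_end <- function(pts, at_start) {
    n <- nrow(pts)
    if (at_start) {
      a <- pts[min(4, n), ]; b <- pts[1, ]
    } else {
      a <- pts[max(1, n - 3), ]; b <- pts[n, ]
    }
    dir <- b - a
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-9) return(pts)
    dir <- dir / nd
    step <- 0.5 * min(header$voxel_size)
    added <- NULL
    p <- b
    repeat {
      p2 <- p + step * dir
      vi <- round(physical_to_voxel(p2, header)) + 1
      if (any(vi < 1) || any(vi > dim(mask)) || !mask[vi[1], vi[2], vi[3]]) break
      added <- rbind(added, p2)
      p <- p2
    }
    if (is.null(added)) return(pts)
    if (at_start) rbind(added[rev(seq_len(nrow(added))), , drop = FALSE], pts)
    else rbind(pts, added)
  }
  pts <- extend_end(pts, at_start = TRUE)
  pts <- extend_end(pts, at_start = FALSE)

  sm <- smooth_polyline(pts, window = 5)
  rs <- resample_polyline(sm, step = 1)
  tg <- central_diff_tangents(rs$points)

  flip <- switch(orientation,
    keep = FALSE,
    flip = TRUE,
    auto = {
      sup <- header$axis_orientation[3, ]
      s_start <- sum(tg[1, ] * sup)
      s_end <- -sum(tg[nrow(tg), ] * sup)
      if (abs(s_start - s_end) > 1e-3) {
        s_end > s_start
      } else {
        # tie (both candidate starts point superiorly, e.g. a U-tube):
        # take the anterior limb (smaller first-axis coordinate) first
        ant <- header$axis_orientation[1, ]
        sum(rs$points[nrow(rs$points), ] * ant) < sum(rs$points[1, ] * ant)
      }
    }
  )
  if (flip) {
    rs$points <- rs$points[rev(seq_len(nrow(rs$points))), , drop = FALSE]
    rs$arc_length <- max(rs$arc_length) - rev(rs$arc_length)
    tg <- -tg[rev(seq_len(nrow(tg))), , drop = FALSE]
  }
  centerline(rs$points, rs$arc_length, tg)
}

#' Place analysis planes along a centerline
#'
#' Planes perpendicular to the centerline at arc positions 0, spacing,
#' 2*spacing, ... up to the total length; the plane normal is the local
#' tangent. The number of planes is always `floor(length/spacing) + 1`.
#'
#' @param cl a [centerline()].
#' @param spacing plane spacing in mm (default 25, the standard test-plane
#'   spacing along the aorta).
#' @return A list of `analysis_plane` objects (fields `center`, `normal`,
#'   `arc_position`).
#' @export
place_planes <- function(cl, spacing = 25) {
  L <- total_length(cl)
  pos <- seq(0, L, by = spacing)
  lapply(pos, function(ss) {
    i <- which.min(abs(cl$arc_length - ss))
    structure(list(center = cl$points[i, ], normal = cl$tangents[i, ],
                   arc_position = ss),
              class = "analysis_plane")
  })
}

#' Construct a flow curve
#'
#' @param arc_position plane arc position, mm.
#' @param times frame times, ms (uniformly spaced).
#' @param q through-plane flow per frame, mL/s.
#' @return An object of class `flow_curve`.
#' @export
flow_curve <- function(arc_position, times, q) {
  stopifnot(length(times) == length(q))
  structure(list(arc_position = arc_position, times = times, q = q),
            class = "flow_curve")
}

#' @export
as.data.frame.flow_curve <- function(x, ...) {
  data.frame(arc_position = x$arc_position, time_ms = x$times, q_ml_s = x$q)
}

# in-plane orthonormal basis for a unit normal
plane_basis <- function(normal) {
  a <- c(0, 0, 0)
  a[which.min(abs(normal))] <- 1
  u <- c(normal[2] * a[3] - normal[3] * a[2],
         normal[3] * a[1] - normal[1] * a[3],
         normal[1] * a[2] - normal[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  list(u = u, v = v)
}

#' Through-plane flow-time curve
#'
#' Samples the analysis plane on a square 2D grid at the minimum voxel
#' dimension, interpolates the velocity trilinearly, gates samples by the
#' nearest-neighbor-sampled segmentation, and integrates the normal
#' velocity component over the in-mask samples: Q(t) = sum (v . n) dA,
#' reported in mL/s.
#'
#' @param ds a [flow_dataset()].
#' @param seg a [segmentation_mask()].
#' @param plane an `analysis_plane` from [place_planes()].
#' @param half_extent optional half-width of the sampling grid, mm
#'   (default: derived from the mask extent around the plane center).
#' @return A [flow_curve()].
#' @export
flow_time_curve <- function(ds, seg, plane, half_extent = NULL) {
  h <- ds$header
  step <- min(h$voxel_size)
  if (is.null(half_extent)) {
    w <- which(seg$whole, arr.ind = TRUE) - 1L
    pw <- voxel_to_physical(w, h)
    dn <- abs((pw - matrix(plane$center, nrow(pw), 3, byrow = TRUE)) %*% plane$normal)
    slab <- dn <= 2 * max(h$voxel_size)
    if (!any(slab)) af_stop("flow_time_curve: plane misses vessel")
    rel <- pw[slab, , drop = FALSE] - matrix(plane$center, sum(slab), 3, byrow = TRUE)
    half_extent <- sqrt(max(rowSums(rel^2))) + 2 * step
  }
  basis <- plane_basis(plane$normal)
  g <- step * seq(-floor(half_extent / step), floor(half_extent / step))
  uv <- as.matrix(expand.grid(a = g, b = g))
  pts <- matrix(plane$center, nrow(uv), 3, byrow = TRUE) +
    uv[, 1] %*% t(basis$u) + uv[, 2] %*% t(basis$v)
  vox <- physical_to_voxel(pts, h)
  nn <- round(vox) + 1
  d3 <- dim(seg$whole)
  inb <- nn[, 1] >= 1 & nn[, 1] <= d3[1] &
    nn[, 2] >= 1 & nn[, 2] <= d3[2] &
    nn[, 3] >= 1 & nn[, 3] <= d3[3]
  inmask <- logical(nrow(nn))
  inmask[inb] <- seg$whole[nn[inb, , drop = FALSE]]
  if (!any(inmask)) af_stop("flow_time_curve: plane misses vessel")
  # keep only the in-plane connected lumen region around the plane center,
  # so a plane through one limb does not also integrate a distant crossing
  ng <- length(g)
  m2 <- matrix(inmask, ng, ng)
  ic <- (ng + 1) %/% 2
  if (!m2[ic, ic]) {
    # center off-mask (partial volume): seed from the nearest in-mask sample
    wim <- which(m2, arr.ind = TRUE)
    sd2 <- (wim[, 1] - ic)^2 + (wim[, 2] - ic)^2
    seedrc <- wim[which.min(sd2), ]
  } else {
    seedrc <- c(ic, ic)
  }
  comp <- matrix(FALSE, ng, ng)
  comp[seedrc[1], seedrc[2]] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-ng, ]
    grown[-ng, ] <- grown[-ng, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -ng]
    grown[, -ng] <- grown[, -ng] | comp[, -1]
    grown <- grown & m2
    if (identical(grown, comp)) break
    comp <- grown
  }
  inmask <- as.vector(comp)
  vox_in <- vox[inmask, , drop = FALSE]
  d <- dim(ds$velocity)
  times <- (seq_len(d[4]) - 1) * h$temporal_resolution
  dA <- step^2
  q <- numeric(d[4])
  for (tt in seq_len(d[4])) {
    vn <- numeric(nrow(vox_in))
    for (k in 1:3) {
      if (abs(plane$normal[k]) < 1e-12) next
      vn <- vn + plane$normal[k] *
        trilinear_interp(ds$velocity[, , , tt, k], vox_in)
    }
    # v [m/s] * area [mm^2] = mL/s
    q[tt] <- sum(vn) * dA
  }
  flow_curve(plane$arc_position, times, q)
}

#' Flow curves for a set of planes
#'
#' @param ds a [flow_dataset()].
#' @param seg a [segmentation_mask()].
#' @param planes list from [place_planes()].
#' @return A list of [flow_curve()]s, classed `flow_curve_set`.
#' @export
flow_time_curves <- function(ds, seg, planes) {
  structure(lapply(planes, function(pl) flow_time_curve(ds, seg, pl)),
            class = "flow_curve_set")
}

#' @export
as.data.frame.flow_curve_set <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

#' Split the aorta mask into AAo, arch and DAo
#'
#' Each mask voxel takes the label of the segment of its nearest
#' centerline point. The centerline is segmented by the
#' superior-inferior component s of its tangent: s > +0.5 is ascending
#' aorta, s < -0.5 descending aorta, the remainder arch. If either
#' threshold yields an empty segment (a straight tube, for instance), the
#' centerline falls back to equal arc-length thirds. The labels always
#' partition the whole mask.
#'
#' @param seg a [segmentation_mask()].
#' @param cl a [centerline()] oriented AAo -> DAo.
#' @param header the [scan_header()] (supplies the superior direction).
#' @return A [segmentation_mask()] with `regions` filled.
#' @export
split_aorta_regions <- function(seg, cl, header) {
  sup <- header$axis_orientation[3, ]
  s_comp <- as.vector(cl$tangents %*% sup)
  lab <- ifelse(s_comp > 0.5, 1L, ifelse(s_comp < -0.5, 3L, 2L))
  if (!any(lab == 1L) || !any(lab == 3L)) {
    # fallback: equal arc-length thirds
    L <- total_length(cl)
    lab <- ifelse(cl$arc_length <= L / 3, 1L,
                  ifelse(cl$arc_length <= 2 * L / 3, 2L, 3L))
  }
  w <- which(seg$whole, arr.ind = TRUE) - 1L
  pw <- voxel_to_physical(w, header)
  best_d <- rep(Inf, nrow(pw))
  best_lab <- rep(2L, nrow(pw))
  for (i in seq_len(nrow(cl$points))) {
    dd <- (pw[, 1] - cl$points[i, 1])^2 + (pw[, 2] - cl$points[i, 2])^2 +
      (pw[, 3] - cl$points[i, 3])^2
    upd <- dd < best_d
    if (any(upd)) {
      best_d[upd] <- dd[upd]
      best_lab[upd] <- lab[i]
    }
  }
  regions <- array(0L, dim(seg$whole))
  regions[seg$whole] <- best_lab
  segmentation_mask(seg$whole, regions)
}
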