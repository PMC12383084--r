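# Deterministic quality-check rasters. Images are composed directly in
# pixel arrays and written with png::writePNG, so repeat runs on identical
# input are byte-identical (no graphics device, no timestamps, no
# antialiasing state).

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# grayscale matrix [w, h] in [0,1] -> rgb array [h, w, 3] (PNG row-major)
gray_to_rgb <- function(m) {
  g <- clamp01(t(m)[rev(seq_len(ncol(m))), , drop = FALSE])
  array(rep(g, 3), c(dim(g), 3))
}

# "hot" colormap for overlays
hot_rgb <- function(x) {
  x <- clamp01(x)
  cbind(clamp01(3 * x), clamp01(3 * x - 1), clamp01(3 * x - 2))
}

# upscale an rgb array by integer factor (nearest neighbor)
upscale_rgb <- function(img, f) {
  if (f <= 1) return(img)
  d <- dim(img)
  out <- array(0, c(d[1] * f, d[2] * f, 3))
  ri <- rep(seq_len(d[1]), each = f)
  ci <- rep(seq_len(d[2]), each = f)
  for (k in 1:3) out[, , k] <- img[ri, ci, k]
  out
}

# place sub-image into canvas at (row, col), 1-based top-left
blit <- function(canvas, img, row, col) {
  d <- dim(img)
  rows <- row:(row + d[1] - 1)
  cols <- col:(col + d[2] - 1)
  keep_r <- rows <= dim(canvas)[1]
  keep_c <- cols <= dim(canvas)[2]
  canvas[rows[keep_r], cols[keep_c], ] <- img[which(keep_r), which(keep_c), , drop = FALSE]
  canvas
}

set_px <- function(img, r, c, col) {
  d <- dim(img)
  ok <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2]
  if (!any(ok)) return(img)
  for (k in 1:3) img[cbind(r[ok], c[ok], k)] <- col[k]
  img
}

draw_segment <- function(img, r0, c0, r1, c1, col) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1
  set_px(img, round(seq(r0, r1, length.out = n)),
         round(seq(c0, c1, length.out = n)), col)
}

# pixel coordinates of a full polyline (all segments rasterized)
polyline_px <- function(r, c) {
  out_r <- integer(0); out_c <- integer(0)
  for (j in seq_len(length(r) - 1)) {
    n <- max(abs(r[j + 1] - r[j]), abs(c[j + 1] - c[j])) + 1
    out_r <- c(out_r, round(seq(r[j], r[j + 1], length.out = n)))
    out_c <- c(out_c, round(seq(c[j], c[j + 1], length.out = n)))
  }
  cbind(out_r, out_c)
}

# 2D mask contour: mask voxels with a 4-neighbor outside the mask
contour2d <- function(m) {
  d <- dim(m)
  pad <- function(dr, dc) {
    out <- matrix(FALSE, d[1], d[2])
    rs <- seq_len(d[1]) + dr; cs <- seq_len(d[2]) + dc
    ok_r <- rs >= 1 & rs <= d[1]; ok_c <- cs >= 1 & cs <= d[2]
    out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  m & !(pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1))
}

# Orthogonal mid-mask slices of magnitude with mask contour and systolic
# speed overlay; slices stacked left to right.
qc_overlay_image <- function(ds, seg = NULL, upscale = 3) {
  d <- dim(ds$magnitude)
  # systolic frame: maximal total speed
  nvox <- prod(d[1:3])
  sp_tot <- vapply(seq_len(d[4]), function(tt) {
    sum(abs(ds$velocity[, , , tt, ])) }, numeric(1))
  tsys <- which.max(sp_tot)
  mag <- ds$magnitude[, , , tsys]
  mag <- mag / max(mag, 1e-12)
  speed3 <- sqrt(ds$velocity[, , , tsys, 1]^2 + ds$velocity[, , , tsys, 2]^2 +
                   ds$velocity[, , , tsys, 3]^2)
  smax <- max(speed3, 1e-12)
  mid <- if (!is.null(seg) && any(seg$whole)) {
    round(colMeans(which(seg$whole, arr.ind = TRUE)))
  } else {
    round(d[1:3] / 2)
  }
  slices <- list(
    list(m = mag[mid[1], , ], s = speed3[mid[1], , ],
         k = if (!is.null(seg)) seg$whole[mid[1], , ]),
    list(m = mag[, mid[2], ], s = speed3[, mid[2], ],
         k = if (!is.null(seg)) seg$whole[, mid[2], ]),
    list(m = mag[, , mid[3]], s = speed3[, , mid[3]],
         k = if (!is.null(seg)) seg$whole[, , mid[3]])
  )
  imgs <- lapply(slices, function(sl) {
    img <- gray_to_rgb(sl$m)
    # speed overlay inside the mask
    if (!is.null(sl$k) && any(sl$k)) {
      kk <- t(sl$k)[rev(seq_len(ncol(sl$k))), , drop = FALSE]
      ss <- t(sl$s)[rev(seq_len(ncol(sl$s))), , drop = FALSE]
      hot <- hot_rgb(ss[kk] / smax)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[kk] <- 0.4 * plane[kk] + 0.6 * hot[, ch]
        img[, , ch] <- plane
      }
      ct <- contour2d(kk)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[ct] <- c(1, 0, 0)[ch]
        img[, , ch] <- plane
      }
    }
    upscale_rgb(img, upscale)
  })
  h <- max(vapply(imgs, function(i) dim(i)[1], numeric(1)))
  w <- sum(vapply(imgs, function(i) dim(i)[2], numeric(1))) + 2 * 2
  canvas <- array(0, c(h, w, 3))
  col <- 1
  for (im in imgs) {
    canvas <- blit(canvas, im, 1, col)
    col <- col + dim(im)[2] + 2
  }
  canvas
}

# Maximum-intensity rendering of the mask (projection along Y) with the
# centerline (green) and plane centers (red).
qc_render_image <- function(ds, seg, cl = NULL, planes = NULL, upscale = 3) {
  h <- ds$header
  proj <- colMeans(aperm(seg$whole, c(2, 1, 3)))  # [X, Z] occupancy
  proj <- proj / max(proj, 1e-12)
  img <- gray_to_rgb(proj)          # rows = Z (flipped), cols = X
  nz <- dim(seg$whole)[3]
  to_px <- function(pts_mm) {
    vox <- physical_to_voxel(pts_mm, h)
    r <- nz - round(vox[, 3])       # flip z for display
    c <- round(vox[, 1]) + 1
    cbind(r, c)
  }
  f <- upscale
  img <- upscale_rgb(img, f)
  scale_px <- function(px) cbind((px[, 1] - 1) * f + (f + 1) %/% 2,
                                 (px[, 2] - 1) * f + (f + 1) %/% 2)
  if (!is.null(cl)) {
    px <- scale_px(to_px(cl$points))
    pl <- polyline_px(px[, 1], px[, 2])
    img <- set_px(img, pl[, 1], pl[, 2], c(0, 1, 0))
  }
  if (!is.null(planes)) {
    for (pl in planes) {
      px <- scale_px(to_px(matrix(pl$center, 1)))
      img <- draw_segment(img, px[1] - f, px[2], px[1] + f, px[2], c(1, 0, 0))
      img <- draw_segment(img, px[1], px[2] - f, px[1], px[2] + f, c(1, 0, 0))
    }
  }
  img
}

# Per-plane flow-curve panel: one polyline per plane on a white canvas.
qc_curves_image <- function(curves, width = 480, height = 320, margin = 20) {
  canvas <- array(1, c(height, width, 3))
  curves <- unclass(curves)
  qs <- unlist(lapply(curves, function(cv) cv$q))
  ts <- curves[[1]]$times
  qr <- range(qs)
  if (diff(qr) == 0) qr <- qr + c(-1, 1)
  tr <- range(ts)
  px_c <- function(t) margin + (t - tr[1]) / diff(tr) * (width - 2 * margin)
  px_r <- function(q) height - margin - (q - qr[1]) / diff(qr) * (height - 2 * margin)
  # axes
  canvas <- draw_segment(canvas, px_r(qr[1]), px_c(tr[1]), px_r(qr[1]), px_c(tr[2]), c(0, 0, 0))
  canvas <- draw_segment(canvas, px_r(qr[1]), px_c(tr[1]), px_r(qr[2]), px_c(tr[1]), c(0, 0, 0))
  if (qr[1] < 0 && qr[2] > 0) {
    canvas <- draw_segment(canvas, px_r(0), px_c(tr[1]), px_r(0), px_c(tr[2]),
                           c(0.8, 0.8, 0.8))
  }
  pal <- cbind(
    c(0.00, 0.85, 0.00, 0.80, 0.55, 0.00, 0.90, 0.35, 0.60, 0.10),
    c(0.45, 0.30, 0.60, 0.55, 0.00, 0.00, 0.60, 0.35, 0.20, 0.10),
    c(0.70, 0.10, 0.20, 0.00, 0.55, 0.80, 0.00, 0.35, 0.60, 0.10)
  )
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    col <- pal[(i - 1) %% nrow(pal) + 1, ]
    px <- polyline_px(px_r(cv$q), px_c(cv$times))
    canvas <- set_px(canvas, px[, 1], px[, 2], col)
  }
  canvas
}

#' Render the quality-check outputs for one dataset
#'
#' Writes deterministic raster images documenting a processing run:
#' orthogonal mid-mask magnitude slices with mask contour and systolic
#' speed overlay (`qc_overlay.png`), a projection rendering of the mask
#' with centerline and analysis-plane positions (`qc_render.png`), the
#' per-plane flow-curve panel (`qc_curves.png`), and a one-line
#' machine-readable verdict stub (`qc_verdict.json`) for subsequent human
#' review (acceptable quality = one contiguous region covering ascending
#' aorta, arch and descending aorta, with no extraneous regions). Panels
#' whose upstream product is missing are skipped and noted in the verdict.
#'
#' @param ds a [flow_dataset()].
#' @param seg,cl,planes,curves upstream products (any may be `NULL`).
#' @param outdir output directory (created if needed).
#' @param flags character vector of QC flags accumulated upstream.
#' @return Character vector of files written, invisibly.
#' @export
render_qc <- function(ds, seg = NULL, cl = NULL, planes = NULL, curves = NULL,
                      outdir, flags = character(0)) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  skipped <- character(0)
  f1 <- file.path(outdir, "qc_overlay.png")
  png::writePNG(qc_overlay_image(ds, seg), f1)
  written <- c(written, f1)
  if (is.null(seg)) skipped <- c(skipped, "mask overlay (no segmentation)")
  if (!is.null(seg)) {
    f2 <- file.path(outdir, "qc_render.png")
    png::writePNG(qc_render_image(ds, seg, cl, planes), f2)
    written <- c(written, f2)
  } else {
    skipped <- c(skipped, "render (no segmentation)")
  }
  if (!is.null(curves) && length(curves) > 0) {
    f3 <- file.path(outdir, "qc_curves.png")
    png::writePNG(qc_curves_image(curves), f3)
    written <- c(written, f3)
  } else {
    skipped <- c(skipped, "flow curves (not computed)")
  }
  verdict <- list(
    review = "pending",
    criteria = "contiguous AAo+arch+DAo, no extraneous regions",
    flags = as.list(flags),
    skipped_panels = as.list(skipped)
  )
  f4 <- file.path(outdir, "qc_verdict.json")
  writeLines(jsonlite::toJSON(verdict, auto_unbox = TRUE), f4)
  written <- c(written, f4)
  invisible(written)
}
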