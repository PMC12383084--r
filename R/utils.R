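# Internal numerical utilities shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

af_stop <- function(...) stop(..., call. = FALSE)

# Run code with a private RNG state so generators do not disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Physical coordinates (mm) of 0-based voxel indices, n x 3.
voxel_to_physical <- function(idx, header) {
  idx <- matrix(idx, ncol = 3)
  scaled <- sweep(idx, 2, header$voxel_size, `*`)
  sweep(scaled %*% header$axis_orientation, 2, header$origin, `+`)
}

# Continuous 0-based voxel indices of physical points (mm), n x 3.
physical_to_voxel <- function(pts, header) {
  pts <- matrix(pts, ncol = 3)
  rel <- sweep(pts, 2, header$origin, `-`) %*% t(header$axis_orientation)
  sweep(rel, 2, header$voxel_size, `/`)
}

# Trilinear interpolation of a 3D array at continuous 0-based voxel
# coordinates (n x 3). Points outside the grid evaluate to 0.
trilinear_interp <- function(arr, pts) {
  d <- dim(arr)
  pts <- matrix(pts, ncol = 3)
  n <- nrow(pts)
  out <- numeric(n)
  ok <- pts[, 1] >= 0 & pts[, 1] <= d[1] - 1 &
    pts[, 2] >= 0 & pts[, 2] <= d[2] - 1 &
    pts[, 3] >= 0 & pts[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  p <- pts[ok, , drop = FALSE]
  i0 <- pmax(pmin(floor(p[, 1]), d[1] - 2), 0)
  j0 <- pmax(pmin(floor(p[, 2]), d[2] - 2), 0)
  k0 <- pmax(pmin(floor(p[, 3]), d[3] - 2), 0)
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  v <- function(di, dj, dk) arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  val <-
    v(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    v(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    v(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    v(1, 1, 0) * fx       * fy       * (1 - fz) +
    v(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    v(1, 0, 1) * fx       * (1 - fy) * fz +
    v(0, 1, 1) * (1 - fx) * fy       * fz +
    v(1, 1, 1) * fx       * fy       * fz
  out[ok] <- val
  out
}

# Shift a 3D array by an integer offset; vacated cells take `fill`.
# shift_array(a, off)[p] == a[p - off] where defined.
shift_array <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- seq.int(1 + o, d[ax]); src[[ax]] <- seq.int(1, d[ax] - o)
    } else {
      dst[[ax]] <- seq.int(1, d[ax] + o); src[[ax]] <- seq.int(1 - o, d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 26-neighborhood offsets (rows), excluding the origin.
neighborhood26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Chamfer (26-neighborhood) Euclidean distance approximation from each
# in-mask voxel to the nearest background voxel, in physical units.
chamfer_edt <- function(mask, spacing) {
  d <- dim(mask)
  dist <- array(0, d)
  dist[mask] <- Inf
  offs <- neighborhood26()
  steps <- sqrt(colSums((t(offs) * spacing)^2))
  repeat {
    changed <- FALSE
    for (m in seq_len(nrow(offs))) {
      cand <- shift_array(dist, offs[m, ], fill = Inf) + steps[m]
      upd <- cand < dist
      if (any(upd)) {
        dist[upd] <- cand[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  dist
}

# Bounding box of a mask with padding, clipped to the grid.
mask_bbox <- function(mask, pad = 1) {
  d <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) af_stop("empty mask")
  lo <- pmax(apply(w, 2, min) - pad, 1)
  hi <- pmin(apply(w, 2, max) + pad, d)
  list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3], lo = lo, hi = hi)
}

# Voxel adjacency graph (26-neighborhood) over in-mask voxels.
# Returns the igraph object, the linear indices of the vertices, their
# array indices (1-based, n x 3) and per-edge physical lengths.
voxel_graph <- function(mask, spacing) {
  d <- dim(mask)
  lin <- which(mask)
  nv <- length(lin)
  vid <- array(0L, d)
  vid[lin] <- seq_len(nv)
  offs <- neighborhood26()
  # half neighborhood: lexicographically positive offsets only
  half <- offs[offs[, 3] > 0 |
                 (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (m in seq_len(nrow(half))) {
    sh <- shift_array(vid, half[m, ], fill = 0L)
    sel <- vid > 0L & sh > 0L
    if (any(sel)) {
      from <- c(from, sh[sel])
      to <- c(to, vid[sel])
      len <- c(len, rep(sqrt(sum((half[m, ] * spacing)^2)), sum(sel)))
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = nv, directed = FALSE)
  arr_ind <- arrayInd(lin, d)
  list(g = g, lin = lin, arr_ind = arr_ind, len = len)
}

# Retain the largest 26-connected component of a logical mask.
largest_component <- function(mask, spacing = c(1, 1, 1)) {
  if (!any(mask)) af_stop("empty mask")
  vg <- voxel_graph(mask, spacing)
  comp <- igraph::components(vg$g)
  keep <- which(comp$membership == which.max(comp$csize))
  out <- array(FALSE, dim(mask))
  out[vg$lin[keep]] <- TRUE
  list(mask = out, n_components = comp$no)
}

# Design matrix of 3D monomials x^i y^j z^k with total degree <= order.
# Returns the matrix plus the exponent table (for labeling coefficients).
poly_design <- function(coords, order) {
  coords <- matrix(coords, ncol = 3)
  ex <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
  ex <- ex[rowSums(ex) <= order, , drop = FALSE]
  ex <- ex[order(rowSums(ex), ex$i, ex$j, ex$k), , drop = FALSE]
  X <- matrix(1, nrow(coords), nrow(ex))
  for (m in seq_len(nrow(ex))) {
    X[, m] <- coords[, 1]^ex$i[m] * coords[, 2]^ex$j[m] * coords[, 3]^ex$k[m]
  }
  colnames(X) <- paste0("x", ex$i, "y", ex$j, "z", ex$k)
  list(X = X, exponents = as.matrix(ex))
}

# Normalize rows of a matrix to unit length (zero rows left untouched).
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

fmt_num <- function(x) sprintf("%.12g", x)
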