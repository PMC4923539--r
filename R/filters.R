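# 3-D array filtering primitives shared by the scanner emulator and the
# segmentation stage. No installed R package provides n-D image filters, so
# these are implemented here: separable Gaussian with half-sample-symmetric
# (reflect) borders — which preserves the array sum exactly for a normalized
# symmetric kernel — a cube median filter with edge-clamped borders, and
# integer-factor block averaging.

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

# convolve along the first dimension of a matrix with reflect padding
conv1_reflect <- function(m, kern) {
  len <- length(kern)
  if (len == 1L) return(m * kern)
  p <- (len - 1L) / 2L
  n <- nrow(m)
  if (p >= n) stop("kernel radius must be smaller than the axis length")
  idx <- c(p:1, 1:n, n:(n - p + 1L))   # reflect: (b a | a b c d | d c)
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_len(len)) {
    out <- out + kern[j] * mp[j:(j + n - 1L), , drop = FALSE]
  }
  out
}

# separable Gaussian filter; sigma_vox length 3, in voxel units
gaussian_filter_3d <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    k <- gauss_kernel_1d(sigma_vox[ax])
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- conv1_reflect(matrix(a, nrow = da[1]), k)
    arr <- aperm(array(m, dim = da), order(perm))
  }
  arr
}

# cube median filter of half-width `radius` voxels, edge-clamped borders
median_filter_3d <- function(arr, radius) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("median filter radius must cover at least 1 voxel")
  d <- dim(arr)
  offs <- as.matrix(expand.grid(dx = -radius:radius, dy = -radius:radius,
                                dz = -radius:radius))
  n <- prod(d)
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  vals <- matrix(0, n, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    jx <- pmin(pmax(ix + offs[o, 1], 1L), d[1])
    jy <- pmin(pmax(iy + offs[o, 2], 1L), d[2])
    jz <- pmin(pmax(iz + offs[o, 3], 1L), d[3])
    vals[, o] <- arr[cbind(jx, jy, jz)]
  }
  array(apply(vals, 1L, stats::median), dim = d)
}

# block average by an integer factor per axis (dims must be divisible)
block_average <- function(arr, factor) {
  factor <- rep_len(as.integer(factor), 3L)
  d <- dim(arr)
  if (any(d %% factor != 0L)) {
    stop("array dims must be divisible by the block-averaging factor")
  }
  dd <- d %/% factor
  a6 <- array(arr, dim = c(factor[1], dd[1], factor[2], dd[2], factor[3], dd[3]))
  out <- apply(a6, c(2L, 4L, 6L), mean)
  array(out, dim = dd)
}

# linear index <-> 0-based (i,j,k) helpers on a given lattice
lin_to_ijk <- function(lin, dims) {
  a <- arrayInd(lin, dims)
  a - 1L
}

# 6-connected components of a logical 3-D mask; returns an integer array with
# 0 outside the mask and component ids 1..k inside (ids ordered by first voxel)
connected_components_3d <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, dim = d))
  pos <- array(0L, dim = d)
  pos[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, d)
  offs <- neighbor_offsets(connectivity)
  efrom <- integer(0); eto <- integer(0)
  for (o in seq_len(nrow(offs))) {
    jx <- ijk[, 1] + offs[o, 1]; jy <- ijk[, 2] + offs[o, 2]
    jz <- ijk[, 3] + offs[o, 3]
    ok <- jx >= 1L & jx <= d[1] & jy >= 1L & jy <= d[2] & jz >= 1L & jz <= d[3]
    if (!any(ok)) next
    nb <- pos[cbind(jx[ok], jy[ok], jz[ok])]
    hit <- nb > 0L
    efrom <- c(efrom, which(ok)[hit])
    eto <- c(eto, nb[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(efrom)) {
    g <- igraph::add_edges(g, rbind(efrom, eto))
  }
  comp <- igraph::components(g)$membership
  out <- array(0L, dim = d)
  out[idx] <- as.integer(comp)
  out
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
           ncol = 3, byrow = TRUE)
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else {
    stop("connectivity must be 6 or 26")
  }
}
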