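# Small fixtures and independent oracles shared across the suite.
# Everything is generated in code; no binary fixtures.

# a fast small specimen: 14 x 14 x 20 voxels, one 2 x 3 mm implant
tiny_spec <- function(seed = 1L, bvtv = 0.3, implants = TRUE) {
  specimen_spec(
    domain_size_mm = c(4.2, 4.2, 6),
    voxel_mm = 0.3,
    cortical_thickness_mm = 0.6,
    target_bvtv = bvtv,
    correlation_length_mm = 0.6,
    implants = if (implants) {
      list(implant_spec(diameter_mm = 2, length_mm = 3, thread_pitch_mm = 0.8,
                        thread_depth_mm = 0.2,
                        axis_entry_point_mm = c(2.1, 2.1, 6),
                        axis_direction = c(0, 0, -1)))
    } else list(),
    rng_seed = seed
  )
}

tiny_config <- function(seed = 1L, ...) {
  # 14 x 14 x 20 lattice: CBCT factor 2 keeps the dims divisible
  pipeline_config(specimen = tiny_spec(seed),
                  cbct_scanner = scanner_spec("cbct", out_voxel_mm = 0.6,
                                              blur_sigma_mm = 0.45,
                                              noise_sd = 5),
                  seed = seed, ...)
}

# brute-force Otsu oracle: exhaustive search over every split between
# consecutive distinct values, class statistics computed from the raw data
otsu_bruteforce <- function(v) {
  lev <- sort(unique(v))
  best <- -Inf; best_t <- NA_real_
  n <- length(v)
  for (t in lev[-length(lev)]) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / n
    bc <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bc > best + 1e-12) { best <- bc; best_t <- t }
  }
  best_t
}

# independent graph-cut energy: plain loops over the lattice, engineered to
# share no code with graphcut_energy
gc_energy_oracle <- function(lab_vec, image, seeds, params, d) {
  v <- as.vector(image$values)
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = params$histogram_bins + 1L)
  bin <- findInterval(v, br, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), params$histogram_bins)
  hist_of <- function(idx) {
    h <- tabulate(bin[idx], nbins = params$histogram_bins) + 1
    h / sum(h)
  }
  pb <- hist_of(seeds$index[seeds$label == 1L])
  pg <- hist_of(seeds$index[seeds$label == 0L])
  e <- 0
  for (i in seq_along(lab_vec)) {
    if (lab_vec[i] == 3L) next
    e <- e + if (lab_vec[i] == 1L) -log(pb[bin[i]]) else -log(pg[bin[i]])
  }
  for (i in seq_along(lab_vec)) {
    if (lab_vec[i] == 3L) next
    ijk <- arrayInd(i, d)
    for (ax in 1:3) {
      jjk <- ijk; jjk[ax] <- jjk[ax] + 1L
      if (jjk[ax] > d[ax]) next
      j <- (jjk[3] - 1L) * d[1] * d[2] + (jjk[2] - 1L) * d[1] + jjk[1]
      if (lab_vec[j] == 3L) next
      if (lab_vec[i] != lab_vec[j]) {
        e <- e + params$lambda_smooth *
          exp(-(v[i] - v[j])^2 / (2 * params$sigma_edge^2))
      }
    }
  }
  e
}

# minimum energy over all labelings of the free voxels, by enumeration
gc_enumeration_min <- function(image, initial, seeds, params) {
  d <- image$dims
  lab0 <- as.vector(initial$labels)
  free <- setdiff(which(lab0 != 3L), seeds$index)
  stopifnot(length(free) <= 16L)
  base <- integer(prod(d))
  base[initial$labels == 3L] <- 3L
  base[seeds$index] <- seeds$label
  best <- Inf
  for (mask in 0:(2^length(free) - 1L)) {
    lab <- base
    lab[free] <- as.integer(bitwAnd(bitwShiftR(mask, seq_along(free) - 1L), 1L))
    e <- gc_energy_oracle(lab, image, seeds, params, d)
    if (e < best) best <- e
  }
  best
}

# random symmetric 3x3 tensor in length-6 component form (xx,yy,zz,xy,yz,xz)
rand_tensor6 <- function() stats::rnorm(6)

tensor6_to_mat <- function(t6) {
  matrix(c(t6[1], t6[4], t6[6],
           t6[4], t6[2], t6[5],
           t6[6], t6[5], t6[3]), 3, 3)
}

rand_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

rotate_tensor6 <- function(t6, R) {
  m <- R %*% tensor6_to_mat(t6) %*% t(R)
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[2, 3], m[1, 3])
}

# eigenvalues via the characteristic cubic (polyroot), an independent route
eig_cubic_oracle <- function(t6) {
  m <- tensor6_to_mat(t6)
  i1 <- sum(diag(m))
  i2 <- (sum(diag(m))^2 - sum(m * m)) / 2
  i3 <- det(m)
  r <- polyroot(c(-i3, i2, -i1, 1))
  sort(Re(r), decreasing = TRUE)
}

# uniaxial bar fixture: nx x ny x nz bone voxels with symmetry constraints and
# a consistent (trapezoidal-weighted) end traction totalling F
bar_problem <- function(n = 6, h = 0.3, F = 10, E = 14400, nu = 0.309,
                        ny = 1L, nz = 1L) {
  lab <- label_map(array(1L, c(n, ny, nz)), h)
  mesh <- assign_materials(voxels_to_hexmesh(lab),
                           table = list(`1` = c(E = E, nu = nu)))
  nd <- mesh$nodes
  cons <- rbind(
    data.frame(node = which(nd[, 1] == 0), comp = 1, value = 0),
    data.frame(node = which(nd[, 2] == 0), comp = 2, value = 0),
    data.frame(node = which(nd[, 3] == 0), comp = 3, value = 0)
  )
  force <- matrix(0, nrow(nd), 3)
  endn <- which(nd[, 1] == max(nd[, 1]))
  w1d <- function(k, n1) if (k == 0 || k == n1) 1 else 2  # trapezoid weights
  w <- vapply(endn, function(i) {
    g <- mesh$node_grid[i, ]
    w1d(g[2], ny) * w1d(g[3], nz)
  }, numeric(1))
  force[endn, 1] <- F * w / sum(w)
  list(mesh = mesh, bcs = list(constraints = cons, force = force),
       end_nodes = endn, L = n * h, A = (ny * h) * (nz * h), E = E, F = F)
}

# irregular foreground blob for the patch test: random voxels plus a connected
# core so the region is nontrivial
blob_labels <- function(seed = 4L, d = c(5, 5, 5), h = 0.25) {
  set.seed(seed)
  arr <- array(0L, dim = d)
  arr[2:4, 2:4, 2:4] <- 1L
  extra <- sample(which(arr == 0L), 12)
  arr[extra] <- 1L
  # keep only voxels 6-connected to the core
  lm <- label_map(arr, h)
  cc <- perifem:::connected_components_3d(arr == 1L, 6L)
  core_id <- cc[3, 3, 3]
  arr[cc != core_id] <- 0L
  label_map(arr, h)
}
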