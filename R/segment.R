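#' Denoise an intensity volume
#'
#' Median filtering (rank filter over a cube neighbourhood, value-set
#' preserving) or Gaussian smoothing (sum-preserving through half-sample
#' reflective borders).
#'
#' @param image a [voxel_image()].
#' @param method `"median"` or `"gaussian"`.
#' @param radius_mm filter scale in mm: the cube half-width for the median
#'   filter (rounded to voxels, at least 1), the smoothing sigma for the
#'   Gaussian.
#' @return a denoised [voxel_image()] on the same lattice.
#' @export
denoise <- function(image, method = c("median", "gaussian"),
                    radius_mm = NULL) {
  stopifnot(inherits(image, "voxel_image"))
  method <- match.arg(method)
  if (is.null(radius_mm)) radius_mm <- image$spacing[1]
  if (method == "median") {
    r <- max(1L, as.integer(round(radius_mm / image$spacing[1])))
    out <- median_filter_3d(image$values, r)
  } else {
    out <- gaussian_filter_3d(image$values, radius_mm / image$spacing)
  }
  voxel_image(out, image$spacing, image$origin)
}

#' Discriminant-analysis (Otsu) threshold
#'
#' Returns the intensity threshold maximizing the between-class variance of
#' the histogram (Otsu's discriminant criterion); ties are broken toward the
#' lower threshold. Voxels with value `<=` threshold form the lower class.
#' Integer-valued data with a modest range use one bin per integer level
#' (making the result exactly equal to an exhaustive search over integer
#' splits); otherwise `bins` equal-width bins over the data range are used,
#' which makes the threshold equivariant under constant intensity shifts.
#'
#' @param image a [voxel_image()] or a numeric vector/array of intensities.
#' @param mask optional logical array/vector selecting the voxels to use.
#' @param bins number of histogram bins for non-integer data.
#' @return the scalar threshold.
#' @export
discriminant_threshold <- function(image, mask = NULL, bins = 256L) {
  otsu_core(image, mask, bins)$threshold
}

# Otsu split plus its between-class variance (used by threshold_segment to
# judge whether a second-stage split is a genuine phase boundary)
otsu_core <- function(image, mask = NULL, bins = 256L) {
  v <- if (inherits(image, "voxel_image")) as.vector(image$values) else
    as.vector(image)
  if (!is.null(mask)) v <- v[as.vector(mask)]
  if (length(v) < 2L || length(unique(v)) < 2L) {
    stop("degenerate input: need at least two distinct intensities")
  }
  int_like <- all(abs(v - round(v)) < 1e-9) && diff(range(v)) <= 4096
  if (int_like) {
    lev <- seq(min(v), max(v))
    counts <- tabulate(round(v) - min(v) + 1L, nbins = length(lev))
    mids <- lev
    edges_upper <- lev + 0.5
  } else {
    br <- seq(min(v), max(v), length.out = bins + 1L)
    counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE),
                       nbins = bins)
    mids <- (br[-1] + br[-length(br)]) / 2
    edges_upper <- br[-1]
  }
  n <- sum(counts)
  w0 <- cumsum(counts) / n
  mu0 <- cumsum(counts * mids) / n
  mu_t <- mu0[length(mu0)]
  valid <- w0 > 0 & w0 < 1
  bc <- rep(-Inf, length(counts))
  bc[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  t_idx <- which.max(bc)   # which.max returns the first (lowest) maximizer
  list(threshold = edges_upper[t_idx], between_variance = bc[t_idx])
}

#' Two-stage discriminant threshold segmentation
#'
#' First Otsu split on the whole image separates implant (above) from the
#' rest; a second Otsu split on the sub-threshold voxels separates bone from
#' background. Output labels: 0 background, 1 bone, 3 implant (no
#' cortical/trabecular distinction is attempted from intensity).
#'
#' Which side of the first split holds two phases depends on the phase
#' proportions: with a dominant bone phase the first threshold isolates the
#' implant (the sub-threshold class then splits into bone/background), but a
#' small implant can leave the first threshold between background and bone
#' (the super-threshold class then splits into bone/implant). Both candidate
#' secondary splits are evaluated and the one with the larger between-class
#' variance (relative to the first stage) wins; if neither reaches
#' `min_stage2_separation` times the first-stage between-class variance the
#' image is two-phase and no implant label is emitted.
#'
#' @param image a [voxel_image()].
#' @param min_stage2_separation fraction of the first-stage between-class
#'   variance below which a secondary split is not a genuine phase boundary.
#' @return a [label_map()].
#' @export
threshold_segment <- function(image, min_stage2_separation = 0.05) {
  stopifnot(inherits(image, "voxel_image"))
  v <- image$values
  s1 <- otsu_core(v)
  t1 <- s1$threshold
  lower <- v <= t1
  strength <- function(s) {
    if (is.null(s)) -Inf else s$between_variance / s1$between_variance
  }
  try_split <- function(mask) {
    tryCatch(otsu_core(v, mask = mask), error = function(e) NULL)
  }
  s_lo <- try_split(lower)
  s_hi <- try_split(!lower)
  r_lo <- strength(s_lo)
  r_hi <- strength(s_hi)
  lab <- array(0L, dim = image$dims)
  if (max(r_lo, r_hi) < min_stage2_separation) {
    lab[!lower] <- 1L   # two-phase image: bone above, background below
  } else if (r_lo >= r_hi) {
    # implant above the first split; bone/background split the rest
    lab[!lower] <- 3L
    lab[lower & v > s_lo$threshold] <- 1L
  } else {
    # background below the first split; bone/implant split the rest
    lab[!lower & v > s_hi$threshold] <- 3L
    lab[!lower & v <= s_hi$threshold] <- 1L
  }
  label_map(lab, image$spacing, image$origin)
}

#' Pseudocolor rendering of an intensity volume
#'
#' Maps intensity monotonically onto a colour ramp — a visualization aid for
#' spotting artifact-darkened bone that thresholding will miss.
#'
#' @param image a [voxel_image()].
#' @param colormap a palette name accepted by [grDevices::hcl.colors()]
#'   (default `"viridis"`, which is luminance-monotone).
#' @param slice optional axial slice index; if given, only that slice is
#'   rendered and an `nx x ny x 3` array is returned.
#' @param file optional PNG path (requires `slice`).
#' @return an RGB array in `[0, 1]`: `dims x 3`, or `nx x ny x 3` for a slice.
#' @export
pseudocolor <- function(image, colormap = "viridis", slice = NULL,
                        file = NULL) {
  stopifnot(inherits(image, "voxel_image"))
  pal <- grDevices::hcl.colors(256L, palette = colormap)  # errors on unknown
  ramp <- grDevices::colorRamp(pal)
  v <- if (is.null(slice)) image$values else image$values[, , slice]
  rng <- range(v)
  z <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else
    array(0, dim = dim(v))
  rgb <- ramp(as.vector(z)) / 255
  out <- array(rgb, dim = c(dim(v), 3L))
  if (!is.null(file)) {
    if (is.null(slice)) stop("PNG output requires a slice index")
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required for PNG output")
    }
    png::writePNG(aperm(out, c(2, 1, 3)), file)
  }
  out
}

#' Segmentation seeds
#'
#' A sparse set of voxel assertions, the reproducible stand-in for the
#' interactive clicks that guide graph-cut refinement: each row asserts that
#' one voxel is background (0), bone (1) or implant (3).
#'
#' @param index integer vector of linear voxel indices (1-based).
#' @param label integer vector of asserted labels, same length.
#' @param dims lattice dims the indices refer to.
#' @return an object of class `segmentation_seeds` (a tibble with attributes).
#' @export
segmentation_seeds <- function(index, label, dims) {
  index <- as.integer(index); label <- as.integer(label)
  stopifnot(length(index) == length(label))
  if (any(index < 1L | index > prod(dims))) stop("seed index out of bounds")
  if (!all(label %in% c(0L, 1L, 3L))) {
    stop("seed labels must be background (0), bone (1) or implant (3)")
  }
  if (anyDuplicated(index)) {
    dup <- index[duplicated(index)]
    if (any(vapply(split(label, index), function(l) length(unique(l)) > 1L,
                   logical(1)))) {
      stop("a voxel is seeded with two different labels")
    }
    keep <- !duplicated(index)
    index <- index[keep]; label <- label[keep]
  }
  structure(tibble::tibble(index = index, label = label),
            dims = as.integer(dims), class = c("segmentation_seeds",
                                               "tbl_df", "tbl", "data.frame"))
}

#' Read / write seed files
#'
#' Plain-text protocol: one seed per line, `i j k label` with 1-based voxel
#' indices.
#'
#' @param file path to the seed file.
#' @param dims lattice dims.
#' @return [segmentation_seeds()].
#' @export
read_seeds <- function(file, dims) {
  m <- as.matrix(utils::read.table(file, col.names = c("i", "j", "k", "label")))
  idx <- m[, 1] + (m[, 2] - 1L) * dims[1] + (m[, 3] - 1L) * dims[1] * dims[2]
  segmentation_seeds(idx, m[, 4], dims)
}

#' @rdname read_seeds
#' @param seeds a [segmentation_seeds()] object.
#' @export
write_seeds <- function(seeds, file) {
  dims <- attr(seeds, "dims")
  ijk <- arrayInd(seeds$index, dims)
  utils::write.table(cbind(ijk, seeds$label), file, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' Programmatic seeds from ground truth (testing protocol)
#'
#' Emulates the user clicks of interactive refinement reproducibly. Per class
#' (bone vs background), candidate voxels are the ground-truth phase eroded by
#' one voxel (a user clicks the interior of a phase, not partial-volume
#' boundary voxels); seeds are then taken at evenly spaced intensity
#' quantiles of the candidates, from the lowest to the highest, so the seeded
#' histograms span each class's full interior intensity range — including
#' artifact-darkened bone. Implant voxels are never seeded.
#'
#' @param truth ground-truth [label_map()].
#' @param image the intensity [voxel_image()] being segmented.
#' @param n_per_class number of seeds per class.
#' @return [segmentation_seeds()].
#' @export
seeds_from_truth <- function(truth, image, n_per_class = 200L) {
  stopifnot(identical(truth$dims, image$dims))
  v <- as.vector(image$values)
  d <- truth$dims
  pick_quantiles <- function(mask, n) {
    core <- mask & !adjacent_to(!mask, d)   # erode by one voxel
    cand <- which(if (any(core)) core else mask)
    n <- min(n, length(cand))
    o <- cand[order(v[cand], cand)]
    unique(o[round(seq(1, length(o), length.out = n))])
  }
  bone <- pick_quantiles(truth$labels == 1L | truth$labels == 2L |
                           truth$labels == 4L, n_per_class)
  bg <- pick_quantiles(truth$labels == 0L, n_per_class)
  segmentation_seeds(c(bone, bg),
                     c(rep(1L, length(bone)), rep(0L, length(bg))),
                     truth$dims)
}

#' Graph-cut parameters
#'
#' @param lambda_smooth pairwise (Potts) weight, >= 0.
#' @param sigma_edge intensity-contrast scale of the boundary term, > 0.
#' @param histogram_bins bins of the seeded intensity histograms, >= 2.
#' @param neighborhood 6 or 26.
#' @return an object of class `graphcut_params`.
#' @export
graphcut_params <- function(lambda_smooth = 2, sigma_edge = 15,
                            histogram_bins = 32L, neighborhood = 6L) {
  stopifnot(lambda_smooth >= 0, sigma_edge > 0, histogram_bins >= 2L,
            neighborhood %in% c(6L, 26L))
  structure(list(lambda_smooth = lambda_smooth, sigma_edge = sigma_edge,
                 histogram_bins = as.integer(histogram_bins),
                 neighborhood = as.integer(neighborhood)),
            class = "graphcut_params")
}

# shared unary setup: seeded-histogram negative log-likelihoods with add-one
# (Laplace) smoothing over `histogram_bins` equal-width bins
gc_unaries <- function(v, seeds, params) {
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = params$histogram_bins + 1L)
  bin <- findInterval(v, br, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > params$histogram_bins] <- params$histogram_bins
  hist_of <- function(idx) {
    h <- tabulate(bin[idx], nbins = params$histogram_bins) + 1
    h / sum(h)
  }
  p_bone <- hist_of(seeds$index[seeds$label == 1L])
  p_bg <- hist_of(seeds$index[seeds$label == 0L])
  list(d_bone = -log(p_bone)[bin], d_bg = -log(p_bg)[bin], bin = bin)
}

#' Seeded graph-cut refinement of a bone/background segmentation
#'
#' Exactly minimizes the two-label energy
#' `E(l) = sum_v D_v(l_v) + lambda * sum_(u,v) w_uv * [l_u != l_v]`
#' over non-implant voxels by a single max-flow/min-cut (the seeded two-label
#' construction with terminal links from the unaries, boundary links
#' `w_uv = exp(-(I_u - I_v)^2 / (2 sigma^2))`, and seeds as infinite-capacity
#' hard constraints). Unaries are negative log-likelihoods from the seeded
#' intensity histograms (add-one smoothed). Voxels labelled implant in
#' `initial` are held fixed and excluded from the optimization.
#'
#' @param image the intensity [voxel_image()].
#' @param initial a [label_map()] (e.g. from [threshold_segment()]); only its
#'   implant label is used (as a hard constraint).
#' @param seeds [segmentation_seeds()] with at least one bone and one
#'   background seed.
#' @param params [graphcut_params()].
#' @return a [label_map()] with labels 0/1/3.
#' @export
graphcut_refine <- function(image, initial, seeds,
                            params = graphcut_params()) {
  stopifnot(inherits(image, "voxel_image"), inherits(initial, "label_map"),
            identical(image$dims, initial$dims))
  if (!any(seeds$label == 1L) || !any(seeds$label == 0L)) {
    stop("need at least one bone seed and one background seed")
  }
  d <- image$dims
  v <- as.vector(image$values)
  implant <- as.vector(initial$labels == 3L)
  active <- which(!implant)
  n <- length(active)
  pos <- integer(prod(d)); pos[active] <- seq_len(n)

  un <- gc_unaries(v, seeds, params)
  cap_s <- un$d_bg[active]     # cut when v ends background-side: pays D(bg)
  cap_t <- un$d_bone[active]   # cut when v ends bone-side: pays D(bone)
  # subtracting min(D_bone, D_bg) per voxel shifts the energy by a constant
  # (argmin unchanged) and leaves at most one terminal link per voxel, which
  # the push-relabel solver repays severalfold
  mshift <- pmin(cap_s, cap_t)
  cap_s <- cap_s - mshift
  cap_t <- cap_t - mshift

  # n-links between active 6/26-neighbours (each undirected pair once)
  offs <- neighbor_offsets(params$neighborhood)
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  ijk <- arrayInd(active, d)
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (o in seq_len(nrow(offs))) {
    jx <- ijk[, 1] + offs[o, 1]; jy <- ijk[, 2] + offs[o, 2]
    jz <- ijk[, 3] + offs[o, 3]
    ok <- jx >= 1L & jx <= d[1] & jy >= 1L & jy <= d[2] & jz >= 1L & jz <= d[3]
    nb_lin <- (jx[ok] - 1L) + (jy[ok] - 1L) * d[1] + (jz[ok] - 1L) * d[1] * d[2] + 1L
    nb <- pos[nb_lin]
    hit <- nb > 0L
    u_id <- seq_len(n)[ok][hit]
    ef <- c(ef, u_id); et <- c(et, nb[hit])
    dI <- v[active[u_id]] - v[active[nb[hit]]]
    ew <- c(ew, params$lambda_smooth *
              exp(-dI^2 / (2 * params$sigma_edge^2)))
  }

  INF <- (sum(cap_s) + sum(cap_t) + sum(ew) + 1) * 10
  sl <- seeds$label[!implant[seeds$index]]
  si <- pos[seeds$index[!implant[seeds$index]]]
  cap_s[si[sl == 1L]] <- INF; cap_t[si[sl == 1L]] <- 0
  cap_t[si[sl == 0L]] <- INF; cap_s[si[sl == 0L]] <- 0

  src <- n + 1L; snk <- n + 2L
  edges <- rbind(cbind(src, seq_len(n)), cbind(seq_len(n), snk),
                 cbind(ef, et))
  caps <- c(cap_s, cap_t, ew)
  keep <- caps > 0
  g <- igraph::make_empty_graph(n = n + 2L, directed = FALSE)
  g <- igraph::add_edges(g, t(edges[keep, , drop = FALSE]))
  mf <- igraph::max_flow(g, source = src, target = snk,
                         capacity = caps[keep])
  side1 <- as.integer(mf$partition1)
  bone_side <- src %in% side1
  member <- logical(n + 2L); member[side1] <- TRUE
  is_bone <- if (bone_side) member[seq_len(n)] else !member[seq_len(n)]

  lab <- array(0L, dim = d)
  lab[active[is_bone]] <- 1L
  lab[implant] <- 3L
  label_map(lab, image$spacing, image$origin)
}

#' Energy of a bone/background labelling under the graph-cut model
#'
#' The same energy [graphcut_refine()] minimizes, evaluated for an arbitrary
#' labelling: unary seeded-histogram costs over non-implant voxels plus the
#' contrast-weighted Potts boundary term. Seed violations score `Inf`.
#'
#' @inheritParams graphcut_refine
#' @param labels a [label_map()] to score.
#' @return scalar energy.
#' @export
graphcut_energy <- function(labels, image, seeds,
                            params = graphcut_params()) {
  d <- image$dims
  v <- as.vector(image$values)
  lab <- as.vector(labels$labels)
  implant <- lab == 3L
  un <- gc_unaries(v, seeds, params)
  sv <- seeds$index[!implant[seeds$index]]
  slab <- seeds$label[!implant[seeds$index]]
  if (any(lab[sv] != slab)) return(Inf)
  e <- sum(ifelse(lab[!implant] == 1L, un$d_bone[!implant],
                  un$d_bg[!implant]))
  offs <- neighbor_offsets(params$neighborhood)
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  act <- which(!implant)
  ijk <- arrayInd(act, d)
  for (o in seq_len(nrow(offs))) {
    jx <- ijk[, 1] + offs[o, 1]; jy <- ijk[, 2] + offs[o, 2]
    jz <- ijk[, 3] + offs[o, 3]
    ok <- jx >= 1L & jx <= d[1] & jy >= 1L & jy <= d[2] & jz >= 1L & jz <= d[3]
    nb <- (jx[ok] - 1L) + (jy[ok] - 1L) * d[1] + (jz[ok] - 1L) * d[1] * d[2] + 1L
    uu <- act[ok]
    live <- !implant[nb]
    uu <- uu[live]; nb <- nb[live]
    dI <- v[uu] - v[nb]
    w <- exp(-dI^2 / (2 * params$sigma_edge^2))
    e <- e + params$lambda_smooth * sum(w * (lab[uu] != lab[nb]))
  }
  e
}

#' Connected-component cleanup of a segmentation
#'
#' Bone components (6-connectivity) smaller than `min_voxels`, or not
#' connected to domain-face bone nor to implant-adjacent bone, are relabelled
#' background. Implant components much smaller than the largest (below 25% of
#' its voxel count — bright speckle noise) are relabelled background, keeping
#' one component per genuine implant.
#'
#' @param labels a [label_map()].
#' @param min_voxels minimum bone component size to keep.
#' @return the cleaned [label_map()].
#' @export
clean_components <- function(labels, min_voxels = 2L) {
  stopifnot(inherits(labels, "label_map"))
  d <- labels$dims
  lab <- labels$labels

  imp_comp <- connected_components_3d(lab == 3L, 6L)
  if (max(imp_comp) > 0L) {
    sizes <- tabulate(imp_comp[imp_comp > 0L], nbins = max(imp_comp))
    drop <- which(sizes < 0.25 * max(sizes))
    if (length(drop)) lab[imp_comp %in% drop] <- 0L
  }

  bone <- lab == 1L | lab == 2L | lab == 4L
  comp <- connected_components_3d(bone, 6L)
  if (max(comp) > 0L) {
    sizes <- tabulate(comp[comp > 0L], nbins = max(comp))
    face <- array(FALSE, dim = d)
    face[c(1L, d[1]), , ] <- TRUE; face[, c(1L, d[2]), ] <- TRUE
    face[, , c(1L, d[3])] <- TRUE
    anchored <- unique(comp[bone & face])
    imp_adj <- adjacent_to(lab == 3L, d)
    anchored <- unique(c(anchored, comp[bone & imp_adj]))
    anchored <- anchored[anchored > 0L]
    keep_id <- intersect(anchored, which(sizes >= min_voxels))
    kill <- bone & !(comp %in% keep_id)
    lab[kill] <- 0L
  }
  label_map(lab, labels$spacing, labels$origin)
}

# voxels with a 6-neighbour inside `mask`
adjacent_to <- function(mask, d) {
  out <- array(FALSE, dim = d)
  offs <- neighbor_offsets(6L)
  idx <- which(mask)
  if (!length(idx)) return(out)
  ijk <- arrayInd(idx, d)
  for (o in seq_len(nrow(offs))) {
    jx <- ijk[, 1] + offs[o, 1]; jy <- ijk[, 2] + offs[o, 2]
    jz <- ijk[, 3] + offs[o, 3]
    ok <- jx >= 1L & jx <= d[1] & jy >= 1L & jy <= d[2] & jz >= 1L & jz <= d[3]
    out[cbind(jx[ok], jy[ok], jz[ok])] <- TRUE
  }
  out
}

#' Dice coefficient between two voxel masks
#'
#' @param a,b logical arrays of equal dims.
#' @return `2|A∩B| / (|A|+|B|)`.
#' @export
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
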