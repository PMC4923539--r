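#' Specimen geometry and morphology specification
#'
#' Describes a synthetic mandibular bone segment: an outer cortical shell and
#' an interior whose trabecular microstructure is a thresholded, anisotropically
#' smoothed Gaussian random field (rod-like struts with rounded marrow voids;
#' the correlation length sets strut thickness, the threshold sets the bone
#' volume fraction BV/TV).
#'
#' @param domain_size_mm length-3, physical extent of the block in mm.
#' @param voxel_mm lattice pitch in mm (single value, cubic voxels).
#' @param cortical_thickness_mm shell thickness in mm (>= 0), applied on all
#'   six domain faces.
#' @param target_bvtv target trabecular bone volume fraction of the interior,
#'   strictly in (0, 1).
#' @param correlation_length_mm trabecular feature size in mm.
#' @param anisotropy length-3 per-axis smoothing-scale ratios (default
#'   isotropic).
#' @param implants list of [implant_spec()] objects.
#' @param rng_seed integer seed; the specimen is a deterministic function of
#'   the spec including this seed.
#' @return an object of class `specimen_spec`.
#' @export
specimen_spec <- function(domain_size_mm = c(6.3, 6.3, 10.8),
                          voxel_mm = 0.3,
                          cortical_thickness_mm = 0.9,
                          target_bvtv = 0.3,
                          correlation_length_mm = 0.8,
                          anisotropy = c(1, 1, 1),
                          implants = list(implant_spec()),
                          rng_seed = 1L) {
  stopifnot(length(domain_size_mm) == 3, all(domain_size_mm > 0),
            voxel_mm > 0, cortical_thickness_mm >= 0,
            correlation_length_mm > 0, length(anisotropy) == 3,
            all(anisotropy > 0))
  if (!(target_bvtv > 0 && target_bvtv < 1)) {
    stop("target_bvtv must be strictly in (0, 1)")
  }
  structure(
    list(domain_size_mm = as.numeric(domain_size_mm),
         voxel_mm = as.numeric(voxel_mm),
         cortical_thickness_mm = as.numeric(cortical_thickness_mm),
         target_bvtv = as.numeric(target_bvtv),
         correlation_length_mm = as.numeric(correlation_length_mm),
         anisotropy = as.numeric(anisotropy),
         implants = implants,
         rng_seed = as.integer(rng_seed)),
    class = "specimen_spec"
  )
}

#' Threaded cylindrical implant specification
#'
#' A regular-neck screw implant idealized as a solid of revolution: a core
#' cylinder of radius `diameter_mm/2 - thread_depth_mm` plus rectangular
#' annular thread rings of outer radius `diameter_mm/2` wherever the axial
#' position modulo `thread_pitch_mm` falls in the first half of the pitch.
#' Defaults follow a regular-neck Ø4.1 mm x 8 mm fixture.
#'
#' @param diameter_mm outer (thread crest) diameter, mm.
#' @param length_mm implant length, mm.
#' @param thread_pitch_mm axial distance between thread rings, mm.
#' @param thread_depth_mm radial depth of the thread, mm
#'   (`diameter_mm > 2*thread_depth_mm >= 0`).
#' @param axis_entry_point_mm physical point (mm) where the implant axis
#'   enters the specimen (the implant occupies axial positions 0..length from
#'   here along `axis_direction`).
#' @param axis_direction unit 3-vector of the implant long axis.
#' @return an object of class `implant_spec`.
#' @export
implant_spec <- function(diameter_mm = 4.1, length_mm = 8,
                         thread_pitch_mm = 0.8, thread_depth_mm = 0.3,
                         axis_entry_point_mm = c(3.15, 3.15, 10.8),
                         axis_direction = c(0, 0, -1)) {
  stopifnot(length_mm > 0, thread_depth_mm >= 0, thread_pitch_mm > 0,
            length(axis_entry_point_mm) == 3, length(axis_direction) == 3)
  if (!(diameter_mm > 2 * thread_depth_mm)) {
    stop("diameter_mm must exceed twice the thread depth")
  }
  nrm <- sqrt(sum(axis_direction^2))
  if (abs(nrm - 1) > 1e-8) stop("axis_direction must be unit-norm")
  structure(
    list(diameter_mm = diameter_mm, length_mm = length_mm,
         thread_pitch_mm = thread_pitch_mm, thread_depth_mm = thread_depth_mm,
         axis_entry_point_mm = as.numeric(axis_entry_point_mm),
         axis_direction = as.numeric(axis_direction) / nrm),
    class = "implant_spec"
  )
}

#' Scanner emulation specification
#'
#' Emulates a micro-CT (high-resolution, noisy) or CBCT (blurred, noisy,
#' block-averaged to a coarser lattice) acquisition of a labelled specimen,
#' including multiplicative metal-artifact darkening of bone between implant
#' pairs.
#'
#' @param modality `"micro_ct"` or `"cbct"`.
#' @param out_voxel_mm output voxel pitch (mm); for CBCT it must be an integer
#'   multiple of the source pitch (block averaging).
#' @param blur_sigma_mm Gaussian point-spread sigma in mm.
#' @param noise_sd additive zero-mean Gaussian noise sd, intensity units.
#' @param artifact_amplitude multiplicative darkening in `[0, 1]` of bone
#'   intensity between implant pairs (0 = no artifact).
#' @param rng_seed integer seed for the noise field.
#' @return an object of class `scanner_spec`.
#' @export
scanner_spec <- function(modality = c("micro_ct", "cbct"),
                         out_voxel_mm = NULL,
                         blur_sigma_mm = 0.15,
                         noise_sd = 8,
                         artifact_amplitude = 0,
                         rng_seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(noise_sd >= 0, blur_sigma_mm >= 0)
  if (artifact_amplitude < 0 || artifact_amplitude > 1) {
    stop("artifact_amplitude must lie in [0, 1]")
  }
  structure(
    list(modality = modality, out_voxel_mm = out_voxel_mm,
         blur_sigma_mm = blur_sigma_mm, noise_sd = noise_sd,
         artifact_amplitude = artifact_amplitude,
         rng_seed = as.integer(rng_seed)),
    class = "scanner_spec"
  )
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a ground-truth trabecular specimen
#'
#' Builds the labelled ground truth: a cortical shell (label 2) of the stated
#' thickness on all six domain faces, and an interior where a seeded,
#' anisotropically smoothed Gaussian random field is thresholded at the
#' quantile that realizes the target BV/TV (label 1 = trabecular bone,
#' label 0 = marrow). Trabecular components not connected to the cortical
#' shell are relabelled marrow, and the threshold count is iterated so the
#' realized BV/TV after cleanup stays within ±0.01 of the target. Implants
#' from the spec are then embedded with [embed_implant()].
#'
#' @param spec a [specimen_spec()].
#' @param embed_implants embed `spec$implants` after generating the bone
#'   (default `TRUE`).
#' @return a [label_map()] ground truth.
#' @export
generate_trabecular_specimen <- function(spec, embed_implants = TRUE) {
  stopifnot(inherits(spec, "specimen_spec"))
  dims <- as.integer(round(spec$domain_size_mm / spec$voxel_mm))
  t_vox <- as.integer(round(spec$cortical_thickness_mm / spec$voxel_mm))
  if (any(dims - 2L * t_vox < 1L)) {
    stop("domain too small to hold the cortical shell plus an interior")
  }
  lab <- array(2L, dim = dims)
  ii <- (t_vox + 1L):(dims[1] - t_vox)
  jj <- (t_vox + 1L):(dims[2] - t_vox)
  kk <- (t_vox + 1L):(dims[3] - t_vox)
  interior <- array(FALSE, dim = dims)
  interior[ii, jj, kk] <- TRUE
  n_int <- sum(interior)

  sigma_vox <- spec$correlation_length_mm / spec$voxel_mm * spec$anisotropy
  field <- with_seed(spec$rng_seed, {
    gaussian_filter_3d(array(stats::rnorm(prod(dims)), dim = dims), sigma_vox)
  })
  fvals <- field[interior]
  ord <- order(fvals, decreasing = TRUE)

  target_n <- round(spec$target_bvtv * n_int)
  tol_n <- 0.01 * n_int
  k <- target_n
  best <- NULL
  for (iter in 1:40) {
    k <- max(1L, min(n_int, as.integer(round(k))))
    bone_int <- logical(n_int)
    bone_int[ord[seq_len(k)]] <- TRUE
    bone <- array(FALSE, dim = dims)
    bone[interior] <- bone_int
    bone <- keep_shell_connected(bone, interior)
    realized_n <- sum(bone)
    best <- bone
    if (abs(realized_n - target_n) <= tol_n) break
    if (iter == 40) {
      stop(sprintf(
        "could not reach target BV/TV %.3f within tolerance; achieved %.3f",
        spec$target_bvtv, realized_n / n_int))
    }
    k <- k + (target_n - realized_n)
  }
  lab[interior] <- ifelse(best[interior], 1L, 0L)
  out <- label_map(lab, rep(spec$voxel_mm, 3), c(0, 0, 0))
  if (embed_implants) {
    for (imp in spec$implants) out <- embed_implant(out, imp)
  }
  out
}

# drop trabecular components (6-connectivity) with no face-neighbour in the
# shell (i.e. not touching the interior boundary layer)
keep_shell_connected <- function(bone, interior) {
  comp <- connected_components_3d(bone, 6L)
  d <- dim(bone)
  # voxels adjacent to the shell: interior voxels whose 6-neighbourhood leaves
  # the interior
  shellcontact <- interior & !erode_interior(interior)
  anchored <- unique(comp[bone & shellcontact])
  anchored <- anchored[anchored > 0L]
  keep <- array(FALSE, dim = d)
  if (length(anchored)) keep[comp %in% anchored] <- TRUE
  bone & keep
}

# interior voxels all of whose 6-neighbours are interior
erode_interior <- function(interior) {
  d <- dim(interior)
  out <- interior
  offs <- neighbor_offsets(6L)
  idx <- which(interior)
  ijk <- arrayInd(idx, d)
  ok <- rep(TRUE, length(idx))
  for (o in seq_len(nrow(offs))) {
    jx <- ijk[, 1] + offs[o, 1]; jy <- ijk[, 2] + offs[o, 2]
    jz <- ijk[, 3] + offs[o, 3]
    inside <- jx >= 1L & jx <= d[1] & jy >= 1L & jy <= d[2] &
      jz >= 1L & jz <= d[3]
    val <- rep(FALSE, length(idx))
    val[inside] <- interior[cbind(jx[inside], jy[inside], jz[inside])]
    ok <- ok & val
  }
  res <- array(FALSE, dim = d)
  res[idx[ok]] <- TRUE
  res
}

#' Embed a threaded implant into a label map
#'
#' Voxels whose centres lie inside the threaded solid of revolution (core
#' cylinder plus thread rings; see [implant_spec()]) are overwritten to
#' label 3 regardless of prior label; all other voxels are unchanged.
#'
#' @param truth a [label_map()].
#' @param imp an [implant_spec()].
#' @return the updated [label_map()].
#' @export
embed_implant <- function(truth, imp) {
  stopifnot(inherits(truth, "label_map"), inherits(imp, "implant_spec"))
  R <- imp$diameter_mm / 2
  dirv <- imp$axis_direction
  p0 <- imp$axis_entry_point_mm
  # exact axis-aligned-box extent of the cylinder: for each axis e,
  # extreme = endpoint·e ± R·sqrt(1 - (dir·e)^2)
  ends <- rbind(p0, p0 + imp$length_mm * dirv)
  half <- R * sqrt(pmax(0, 1 - dirv^2))
  lo <- pmin(ends[1, ], ends[2, ]) - half
  hi <- pmax(ends[1, ], ends[2, ]) + half
  dom_lo <- truth$origin
  dom_hi <- truth$origin + truth$dims * truth$spacing
  if (any(lo < dom_lo - 1e-9) || any(hi > dom_hi + 1e-9)) {
    stop("implant extends outside the specimen domain")
  }
  cx <- axis_centers(truth$dims[1], truth$spacing[1], truth$origin[1])
  cy <- axis_centers(truth$dims[2], truth$spacing[2], truth$origin[2])
  cz <- axis_centers(truth$dims[3], truth$spacing[3], truth$origin[3])
  px <- rep(cx, times = truth$dims[2] * truth$dims[3]) - p0[1]
  py <- rep(rep(cy, each = truth$dims[1]), times = truth$dims[3]) - p0[2]
  pz <- rep(cz, each = truth$dims[1] * truth$dims[2]) - p0[3]
  s <- px * dirv[1] + py * dirv[2] + pz * dirv[3]
  r2 <- (px - s * dirv[1])^2 + (py - s * dirv[2])^2 + (pz - s * dirv[3])^2
  r_core <- R - imp$thread_depth_mm
  in_len <- s >= 0 & s <= imp$length_mm
  in_thread <- (s %% imp$thread_pitch_mm) < imp$thread_pitch_mm / 2
  inside <- in_len & (r2 <= r_core^2 | (in_thread & r2 <= R^2))
  lab <- truth$labels
  lab[inside] <- 3L
  label_map(lab, truth$spacing, truth$origin)
}

#' Homogenize the trabecular interior into a cancellous block
#'
#' Every voxel labelled marrow (0) or trabecular bone (1) becomes the
#' homogenized cancellous block (label 4); cortical (2) and implant (3) voxels
#' are untouched. This is the ground truth of the simplified
#' (CBCT-resolution) model in which cancellous bone is a nonporous continuum.
#'
#' @param truth a [label_map()] ground truth.
#' @return the homogenized [label_map()].
#' @export
make_homogenized_truth <- function(truth) {
  stopifnot(inherits(truth, "label_map"))
  lab <- truth$labels
  lab[lab == 0L | lab == 1L] <- 4L
  label_map(lab, truth$spacing, truth$origin)
}

#' Two-implant specimen for metal-artifact demonstrations
#'
#' A wider bone segment holding two implants at 4 mm edge-to-edge spacing —
#' the configuration in which inter-implant artifact shading defeats plain
#' thresholding and motivates graph-cut refinement. Same lattice pitch and
#' morphology parameters as [specimen_spec()] defaults.
#'
#' @param rng_seed integer seed.
#' @return a [specimen_spec()] with two implants.
#' @export
two_implant_specimen_spec <- function(rng_seed = 1L) {
  specimen_spec(
    domain_size_mm = c(16.8, 6.3, 10.8),
    implants = list(
      implant_spec(axis_entry_point_mm = c(4.35, 3.15, 10.8)),
      implant_spec(axis_entry_point_mm = c(12.45, 3.15, 10.8))
    ),
    rng_seed = rng_seed
  )
}

#' Default per-label base scan intensities
#'
#' Arbitrary units chosen so that discriminant thresholding separates implant
#' from bone from background in the noiseless limit: background/marrow 20,
#' bone (trabecular, cortical, cancellous block) 100, implant 230.
#'
#' @return a named numeric vector indexed by label value.
#' @export
default_intensities <- function() {
  c(`0` = 20, `1` = 100, `2` = 100, `3` = 230, `4` = 100)
}

#' Emulate a scan of a labelled specimen
#'
#' Assigns per-label base intensities, darkens bone multiplicatively by
#' `(1 - artifact_amplitude * w(x))` where the weight `w` is a smooth bump
#' peaking (value exactly 1) at the midpoint between the two implants' axis
#' centroids and vanishing far from them (`w = 0` when fewer than two implants
#' are present), applies a Gaussian blur, adds Gaussian noise, and — for CBCT —
#' block-averages down to the output pitch (which must be an integer multiple
#' of the source pitch). Deterministic given `scanner$rng_seed`.
#'
#' @param truth a [label_map()].
#' @param scanner a [scanner_spec()].
#' @param intensities named per-label base intensities
#'   (default [default_intensities()]).
#' @return a [voxel_image()].
#' @export
simulate_scan <- function(truth, scanner, intensities = default_intensities()) {
  stopifnot(inherits(truth, "label_map"), inherits(scanner, "scanner_spec"))
  lab <- truth$labels
  img <- array(unname(intensities[as.character(lab)]), dim = truth$dims)
  if (anyNA(img)) stop("intensity table does not cover all labels present")

  if (scanner$artifact_amplitude > 0) {
    w <- interimplant_weight(truth)
    bone <- lab == 1L | lab == 2L | lab == 4L
    img[bone] <- img[bone] * (1 - scanner$artifact_amplitude * w[bone])
  }
  if (scanner$blur_sigma_mm > 0) {
    img <- gaussian_filter_3d(img, scanner$blur_sigma_mm / truth$spacing)
  }
  if (scanner$noise_sd > 0) {
    img <- img + with_seed(scanner$rng_seed, {
      array(stats::rnorm(length(img), sd = scanner$noise_sd), dim = dim(img))
    })
  }
  spacing <- truth$spacing
  if (scanner$modality == "cbct") {
    out_mm <- if (is.null(scanner$out_voxel_mm)) {
      # default: the largest integer factor <= 3 that divides the lattice
      f <- max(c(1L, Filter(function(k) all(truth$dims %% k == 0L), 2:3)))
      f * truth$spacing[1]
    } else scanner$out_voxel_mm
    fac <- out_mm / truth$spacing
    if (any(abs(fac - round(fac)) > 1e-9) || any(round(fac) < 1)) {
      stop("cbct out_voxel_mm must be an integer multiple of the source pitch")
    }
    img <- block_average(img, as.integer(round(fac)))
    spacing <- truth$spacing * round(fac)
  }
  voxel_image(img, spacing, truth$origin)
}

# smooth weight field peaking at the midpoint between the two implant-axis
# centroids; zero when fewer than two implants exist in the label map
interimplant_weight <- function(truth) {
  comp <- connected_components_3d(truth$labels == 3L, 6L)
  ncomp <- max(comp)
  w <- array(0, dim = truth$dims)
  if (ncomp < 2L) return(w)
  sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
  two <- order(sizes, decreasing = TRUE)[1:2]
  cents <- lapply(two, function(cid) {
    ijk <- arrayInd(which(comp == cid), truth$dims)
    truth$origin + (colMeans(ijk) - 0.5) * truth$spacing
  })
  m <- (cents[[1]] + cents[[2]]) / 2
  s <- sqrt(sum((cents[[1]] - cents[[2]])^2)) / 4
  cx <- axis_centers(truth$dims[1], truth$spacing[1], truth$origin[1]) - m[1]
  cy <- axis_centers(truth$dims[2], truth$spacing[2], truth$origin[2]) - m[2]
  cz <- axis_centers(truth$dims[3], truth$spacing[3], truth$origin[3]) - m[3]
  d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  exp(-d2 / (2 * s^2))
}

#' Interior bone volume fraction of a label map
#'
#' BV/TV measured by voxel counting over the interior (non-cortical,
#' non-implant) region: label-1 voxels divided by label-0 plus label-1 voxels.
#'
#' @param truth a [label_map()].
#' @return a single number in `[0, 1]`.
#' @export
bvtv <- function(truth) {
  n1 <- sum(truth$labels == 1L)
  n0 <- sum(truth$labels == 0L)
  if (n0 + n1 == 0L) return(NA_real_)
  n1 / (n0 + n1)
}
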