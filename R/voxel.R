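#' Voxel intensity volume
#'
#' A 3-D scalar intensity grid with physical spacing, the in-memory stand-in
#' for a micro-CT or CBCT stack. Values are arbitrary intensity units.
#'
#' The coordinate convention is: voxel indices are 0-based internally and the
#' physical position of a voxel centre is `origin + (index + 0.5) * spacing`.
#'
#' @param values numeric 3-D array of intensities.
#' @param spacing numeric length-3, voxel pitch in mm (all > 0).
#' @param origin numeric length-3, physical position (mm) of the corner of
#'   voxel (0,0,0).
#' @return an object of class `voxel_image` with fields `values`, `dims`,
#'   `spacing`, `origin`.
#' @export
voxel_image <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3-D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be strictly positive")
  }
  dims <- dim(values)
  if (any(dims < 1L)) stop("all dims must be >= 1")
  structure(
    list(values = values, dims = as.integer(dims),
         spacing = spacing, origin = rep_len(as.numeric(origin), 3L)),
    class = "voxel_image"
  )
}

LABEL_SET <- c(background = 0L, trabecular = 1L, cortical = 2L,
               implant = 3L, cancellous_block = 4L)

#' Label volume
#'
#' A 3-D integer grid on the same lattice as a [voxel_image()]. Labels:
#' 0 background/marrow, 1 trabecular bone, 2 cortical bone, 3 implant,
#' 4 homogenized cancellous block.
#'
#' @param labels integer 3-D array with values in `{0,1,2,3,4}`.
#' @inheritParams voxel_image
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3-D array")
  lab <- as.integer(labels)
  if (anyNA(lab) || !all(lab %in% LABEL_SET)) {
    stop("labels must be integers in {0,1,2,3,4}")
  }
  arr <- array(lab, dim = dim(labels))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("`spacing` must be strictly positive")
  structure(
    list(labels = arr, dims = as.integer(dim(labels)),
         spacing = spacing, origin = rep_len(as.numeric(origin), 3L)),
    class = "label_map"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  cat("<voxel_image> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, range [", signif(min(x$values), 5), ", ",
      signif(max(x$values), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = LABEL_SET))
  names(tab) <- names(LABEL_SET)
  cat("<label_map> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n", sep = "")
  print(tab)
  invisible(x)
}

# physical centre coordinates of every voxel along one axis (0-based index)
axis_centers <- function(n, spacing, origin) origin + (seq_len(n) - 0.5) * spacing

#' Physical voxel-centre coordinates
#'
#' @param x a `voxel_image` or `label_map`.
#' @return a list of three numeric vectors (mm), one per axis.
#' @export
voxel_centers <- function(x) {
  lapply(1:3, function(a) axis_centers(x$dims[a], x$spacing[a], x$origin[a]))
}

#' Write a volume as raw binary with a JSON sidecar
#'
#' The volume is written as a little-endian raw array (`<prefix>.raw`,
#' column-major / x-fastest) plus `<prefix>.json` holding dims, spacing,
#' origin, dtype and, for label maps, the label dictionary.
#'
#' @param x a `voxel_image` or `label_map`.
#' @param prefix path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_volume <- function(x, prefix) {
  is_lab <- inherits(x, "label_map")
  vals <- if (is_lab) x$labels else x$values
  dtype <- if (is_lab) "int32" else "float64"
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  if (is_lab) {
    writeBin(as.integer(vals), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = 8L, endian = "little")
  }
  meta <- list(dims = x$dims, spacing_mm = x$spacing, origin_mm = x$origin,
               dtype = dtype, order = "x-fastest",
               kind = if (is_lab) "label_map" else "voxel_image")
  if (is_lab) meta$labels <- as.list(LABEL_SET)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a volume written by [write_volume()]
#'
#' @param prefix path prefix used at write time.
#' @return a `voxel_image` or `label_map`, per the sidecar metadata.
#' @export
read_volume <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  if (identical(meta$dtype, "int32")) {
    v <- readBin(con, integer(), n = n, size = 4L, endian = "little")
  } else {
    v <- readBin(con, double(), n = n, size = 8L, endian = "little")
  }
  arr <- array(v, dim = meta$dims)
  if (identical(meta$kind, "label_map")) {
    label_map(arr, meta$spacing_mm, meta$origin_mm)
  } else {
    voxel_image(arr, meta$spacing_mm, meta$origin_mm)
  }
}

#' Export a volume as a stack of 2-D TIFF slices
#'
#' Slices are taken along the third (axial) axis. Intensities are rescaled to
#' `[0, 1]`; the affine rescaling and lattice metadata are recorded in a JSON
#' sidecar so [read_tiff_stack()] can restore the original values.
#'
#' @param x a `voxel_image`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tiff_stack <- function(x, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lo <- min(x$values); hi <- max(x$values)
  scale <- if (hi > lo) hi - lo else 1
  for (k in seq_len(x$dims[3])) {
    sl <- (x$values[, , k] - lo) / scale
    # tiff expects row-major images; transpose so axis 1 = image rows
    tiff::writeTIFF(t(sl), file.path(dir, sprintf("slice_%04d.tif", k)),
                    bits.per.sample = 16L)
  }
  jsonlite::write_json(
    list(dims = x$dims, spacing_mm = x$spacing, origin_mm = x$origin,
         value_min = lo, value_scale = scale, n_slices = x$dims[3]),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Import a TIFF slice stack written by [write_tiff_stack()]
#'
#' @param dir directory holding the slices and `stack.json`.
#' @return a `voxel_image`. Values are restored up to 16-bit quantization.
#' @export
read_tiff_stack <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF import")
  }
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  arr <- array(0, dim = meta$dims)
  for (k in seq_len(meta$n_slices)) {
    sl <- tiff::readTIFF(file.path(dir, sprintf("slice_%04d.tif", k)))
    arr[, , k] <- t(sl) * meta$value_scale + meta$value_min
  }
  voxel_image(arr, meta$spacing_mm, meta$origin_mm)
}
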