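# tensor fields are stored as E x 6 matrices of tensor components in the
# order (xx, yy, zz, xy, yz, xz); shear entries are tensor (not engineering)
# components.

tensor_field <- function(m, kind = c("strain", "stress")) {
  kind <- match.arg(kind)
  colnames(m) <- c("xx", "yy", "zz", "xy", "yz", "xz")
  structure(list(values = m, kind = kind), class = "element_tensor_field")
}

#' @export
print.element_tensor_field <- function(x, ...) {
  cat("<element_tensor_field> ", nrow(x$values), " elements, kind = ",
      x$kind, "\n", sep = "")
  invisible(x)
}

#' Element centroid strains from a displacement field
#'
#' Small-strain tensor `eps = (grad u + grad u^T) / 2` evaluated at each
#' element centroid via the trilinear shape-function gradients (which are
#' exact for any linear displacement field).
#'
#' @param mesh a `hex_mesh`.
#' @param u an N x 3 displacement matrix or an `fe_solution`.
#' @return an `element_tensor_field` of kind `"strain"`.
#' @export
element_strain <- function(mesh, u) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (inherits(u, "fe_solution")) u <- u$u
  # centroid gradient of shape i: dN_i/dx_q = sign_iq / (4h)
  G <- HEX_SIGNS / (4 * mesh$h)   # 8 x 3
  el <- mesh$elems
  grad <- array(0, dim = c(nrow(el), 3, 3))   # grad[e, p, q] = du_p/dx_q
  for (p in 1:3) {
    up <- matrix(u[el, p], nrow = nrow(el))   # E x 8
    for (q in 1:3) grad[, p, q] <- up %*% G[, q]
  }
  eps <- cbind(
    xx = grad[, 1, 1], yy = grad[, 2, 2], zz = grad[, 3, 3],
    xy = (grad[, 1, 2] + grad[, 2, 1]) / 2,
    yz = (grad[, 2, 3] + grad[, 3, 2]) / 2,
    xz = (grad[, 1, 3] + grad[, 3, 1]) / 2
  )
  tensor_field(eps, "strain")
}

#' Element stresses from strains (isotropic Hooke's law)
#'
#' `sigma = lambda tr(eps) I + 2 mu eps`, with the Lame parameters from each
#' element's `(E, nu)`.
#'
#' @param strain an `element_tensor_field` of kind `"strain"`.
#' @param mesh the `hex_mesh` carrying per-element materials.
#' @return an `element_tensor_field` of kind `"stress"` (MPa).
#' @export
element_stress <- function(strain, mesh) {
  stopifnot(inherits(strain, "element_tensor_field"),
            strain$kind == "strain", !is.null(mesh$E))
  lam <- mesh$E * mesh$nu / ((1 + mesh$nu) * (1 - 2 * mesh$nu))
  mu <- mesh$E / (2 * (1 + mesh$nu))
  e <- strain$values
  tr <- e[, 1] + e[, 2] + e[, 3]
  s <- cbind(
    xx = lam * tr + 2 * mu * e[, 1],
    yy = lam * tr + 2 * mu * e[, 2],
    zz = lam * tr + 2 * mu * e[, 3],
    xy = 2 * mu * e[, 4], yz = 2 * mu * e[, 5], xz = 2 * mu * e[, 6]
  )
  tensor_field(s, "stress")
}

as_tensor_rows <- function(x) {
  if (inherits(x, "element_tensor_field")) return(x$values)
  if (is.matrix(x) && ncol(x) == 6) return(x)
  if (is.matrix(x) && all(dim(x) == c(3, 3))) {
    return(matrix(c(x[1, 1], x[2, 2], x[3, 3], x[1, 2], x[2, 3], x[1, 3]),
                  nrow = 1))
  }
  if (is.numeric(x) && length(x) == 6) return(matrix(x, nrow = 1))
  stop("expected a tensor field, an E x 6 matrix, a 3 x 3 matrix or a ",
       "length-6 vector")
}

#' Von Mises equivalent stress
#'
#' `sqrt(3/2 s:s)` with `s` the deviatoric part — rotation invariant, zero iff
#' the tensor is hydrostatic. This is the "equivalent stress" convention of
#' standard FE packages.
#'
#' @param sigma a stress `element_tensor_field`, E x 6 matrix, 3 x 3 matrix or
#'   length-6 vector (components xx, yy, zz, xy, yz, xz).
#' @return numeric vector of non-negative scalars (one per element).
#' @export
von_mises <- function(sigma) {
  s <- as_tensor_rows(sigma)
  sqrt(pmax(0, 0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                        (s[, 3] - s[, 1])^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
}

#' Ordered principal values of symmetric tensors
#'
#' Eigenvalues in descending order (`v1 >= v2 >= v3`): `v1` is the tensile
#' measure, `-v3` the compressive measure.
#'
#' @inheritParams von_mises
#' @param tensor tensor input, same formats as [von_mises()].
#' @return an E x 3 matrix with columns `v1 >= v2 >= v3`.
#' @export
principal_values <- function(tensor) {
  m <- as_tensor_rows(tensor)
  out <- matrix(0, nrow(m), 3L)
  for (e in seq_len(nrow(m))) {
    Tm <- matrix(c(m[e, 1], m[e, 4], m[e, 6],
                   m[e, 4], m[e, 2], m[e, 5],
                   m[e, 6], m[e, 5], m[e, 3]), 3, 3)
    out[e, ] <- sort(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE)
  }
  colnames(out) <- c("v1", "v2", "v3")
  out
}

#' Von-Mises-type equivalent strain
#'
#' `sqrt(2/3 e:e)` with `e` the deviatoric strain (tensor shear components):
#' the deviatoric equivalent-strain convention, which for an isotropic
#' material satisfies `von_mises(sigma) = 3 mu * equivalent_strain(eps)`.
#' Zero for purely volumetric strain.
#'
#' @param eps a strain `element_tensor_field` or tensor input as in
#'   [von_mises()].
#' @return numeric vector of non-negative scalars.
#' @export
equivalent_strain <- function(eps) {
  e <- as_tensor_rows(eps)
  tr3 <- (e[, 1] + e[, 2] + e[, 3]) / 3
  d1 <- e[, 1] - tr3; d2 <- e[, 2] - tr3; d3 <- e[, 3] - tr3
  ee <- d1^2 + d2^2 + d3^2 + 2 * (e[, 4]^2 + e[, 5]^2 + e[, 6]^2)
  sqrt(pmax(0, 2 / 3 * ee))
}

MEASURES <- c("equivalent_stress", "tensile_stress", "compressive_stress",
              "equivalent_strain", "tensile_strain", "compressive_strain")

# the six scalar measures for every element; compressive reported as positive
element_measures <- function(stress, strain) {
  ps <- principal_values(stress)
  pe <- principal_values(strain)
  tibble::tibble(
    equivalent_stress = von_mises(stress),
    tensile_stress = pmax(ps[, 1], 0),
    compressive_stress = pmax(-ps[, 3], 0),
    equivalent_strain = equivalent_strain(strain),
    tensile_strain = pmax(pe[, 1], 0),
    compressive_strain = pmax(-pe[, 3], 0)
  )
}

#' Interface summary of the six stress/strain measures
#'
#' Maximum and arithmetic mean, over the implant-bone interface elements, of
#' equivalent (von Mises) stress, tensile stress (first principal, clamped at
#' 0), compressive stress (minus third principal, clamped at 0), and the three
#' strain counterparts. Statistics are taken over bone elements only.
#'
#' @param stress,strain `element_tensor_field`s on the mesh.
#' @param mesh the `hex_mesh`.
#' @param interface integer element ids, e.g. from [find_interface()].
#' @param variant tag for the model variant (`"refined"`/`"simplified"`).
#' @return a tibble of class `interface_summary` with columns `measure`,
#'   `max`, `mean`, plus attributes `variant` and `n_interface`.
#' @export
summarize_interface <- function(stress, strain, mesh, interface,
                                variant = "refined") {
  if (length(interface) == 0L) stop("interface element set is empty")
  meas <- element_measures(
    tensor_field(stress$values[interface, , drop = FALSE], "stress"),
    tensor_field(strain$values[interface, , drop = FALSE], "strain")
  )
  out <- tibble::tibble(
    measure = MEASURES,
    max = unname(vapply(meas, max, numeric(1))),
    mean = unname(vapply(meas, mean, numeric(1)))
  )
  structure(out, variant = variant, n_interface = length(interface),
            class = c("interface_summary", class(out)))
}

#' @export
print.interface_summary <- function(x, ...) {
  cat("Implant-bone interface summary (", attr(x, "variant"), " model, ",
      attr(x, "n_interface"), " interface elements)\n", sep = "")
  NextMethod()
}

#' Compare refined and simplified interface summaries
#'
#' Per-measure percent change of the maximum and the mean, defined as
#' `100 * (refined - simplified) / simplified`. Percent change is `NA` (with a
#' `defined` flag) where the simplified value is not strictly positive.
#'
#' @param refined,simplified `interface_summary` objects from paired models
#'   under identical load.
#' @return a tibble of class `comparison_report` with columns `measure`,
#'   `stat` (max/mean), `refined`, `simplified`, `pct_change`, `defined`.
#' @export
compare_models <- function(refined, simplified) {
  long <- function(s, name) {
    tidyr::pivot_longer(tibble::as_tibble(s), c("max", "mean"),
                        names_to = "stat", values_to = name)
  }
  out <- dplyr::inner_join(long(refined, "refined"),
                           long(simplified, "simplified"),
                           by = c("measure", "stat"))
  out$defined <- out$simplified > 0
  out$pct_change <- ifelse(out$defined,
                           100 * (out$refined - out$simplified) /
                             out$simplified, NA_real_)
  structure(out, class = c("comparison_report", class(out)))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Refined vs simplified interface comparison",
      " (pct_change = 100*(refined-simplified)/simplified)\n", sep = "")
  NextMethod()
}

#' Write a comparison report as TSV
#'
#' @param report a `comparison_report`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_comparison_tsv <- function(report, file) {
  utils::write.table(as.data.frame(report), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.interface_summary <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.interface_summary <- function(x, ...) {
  tibble::tibble(
    variant = attr(x, "variant"),
    n_interface = attr(x, "n_interface"),
    max_equivalent_stress = x$max[x$measure == "equivalent_stress"],
    mean_equivalent_stress = x$mean[x$measure == "equivalent_stress"],
    mean_equivalent_strain = x$mean[x$measure == "equivalent_strain"]
  )
}

#' @export
tidy.comparison_report <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    mean_stress_pct_change =
      x$pct_change[x$measure == "equivalent_stress" & x$stat == "mean"],
    max_stress_pct_change =
      x$pct_change[x$measure == "equivalent_stress" & x$stat == "max"],
    mean_strain_pct_change =
      x$pct_change[x$measure == "equivalent_strain" & x$stat == "mean"]
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of the interface comparison
#'
#' Mirrors the paired max/mean bar charts of the two model variants.
#'
#' @param object a `comparison_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.comparison_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("refined", "simplified"),
                            names_to = "model", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$value,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "stress (MPa) / strain (-)",
                  title = "Implant-bone interface: refined vs simplified")
}

#' Heatmap of one axial slice of a volume
#'
#' @param object a `voxel_image` or `label_map`.
#' @param slice axial (third-axis) slice index; default the middle slice.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.voxel_image <- function(object, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(object$dims[3] / 2)
  vals <- if (inherits(object, "label_map")) object$labels else object$values
  ctr <- voxel_centers(object)
  df <- expand.grid(x = ctr[[1]], y = ctr[[2]])
  df$value <- as.vector(vals[, , slice])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("axial slice %d", slice))
  if (inherits(object, "label_map")) {
    p + ggplot2::scale_fill_viridis_c(name = "label")
  } else {
    p + ggplot2::scale_fill_viridis_c(name = "intensity")
  }
}

#' @export
autoplot.label_map <- autoplot.voxel_image

#' Export mesh, fields and measures as a legacy-ASCII VTK unstructured grid
#'
#' Writes hexahedron cells with cell data (the six scalar measures, material
#' label, Young's modulus, interface flag) and point data (displacement), in
#' the plain-text legacy VTK format readable by standard VTK tools.
#'
#' @param mesh a `hex_mesh` with materials assigned.
#' @param stress,strain `element_tensor_field`s (optional).
#' @param solution an `fe_solution` (optional, for point displacements).
#' @param interface integer element ids flagged as interface (optional).
#' @param path output `.vtk` file path.
#' @return `path`, invisibly.
#' @export
export_fields <- function(mesh, path, stress = NULL, strain = NULL,
                          solution = NULL, interface = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  ne <- nrow(mesh$elems); nn <- nrow(mesh$nodes)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("peri-implant micro-FE fields")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", nn, " double")
  utils::write.table(format(mesh$nodes, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  wl("CELLS ", ne, " ", ne * 9L)
  utils::write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  wl("CELL_TYPES ", ne)
  writeLines(rep("12", ne), con)
  wl("CELL_DATA ", ne)
  write_scalar <- function(name, v, type = "double") {
    wl("SCALARS ", name, " ", type, " 1")
    wl("LOOKUP_TABLE default")
    writeLines(format(v, digits = 17, trim = TRUE), con)
  }
  write_scalar("material_label", mesh$label, "int")
  if (!is.null(mesh$E)) write_scalar("youngs_modulus_MPa", mesh$E)
  if (!is.null(interface)) {
    flag <- integer(ne); flag[interface] <- 1L
    write_scalar("interface_flag", flag, "int")
  }
  if (!is.null(stress) && !is.null(strain)) {
    meas <- element_measures(stress, strain)
    for (m in MEASURES) write_scalar(m, meas[[m]])
  }
  if (!is.null(solution)) {
    u <- if (inherits(solution, "fe_solution")) solution$u else solution
    wl("POINT_DATA ", nn)
    wl("VECTORS displacement_mm double")
    utils::write.table(format(u, digits = 17, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read back a legacy-ASCII VTK unstructured grid written by [export_fields()]
#'
#' A minimal reader for round-trip checks: returns points, hexahedron
#' connectivity, cell scalars and point vectors.
#'
#' @param path the `.vtk` file.
#' @return a list with `points`, `cells` (1-based), `cell_data` (named list),
#'   `point_data` (named list).
#' @export
read_vtk_legacy <- function(path) {
  ln <- readLines(path)
  find1 <- function(pat) grep(pat, ln)[1]
  ip <- find1("^POINTS ")
  np <- as.integer(strsplit(ln[ip], " +")[[1]][2])
  pts <- matrix(scan(text = ln[(ip + 1):(ip + np)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  ic <- find1("^CELLS ")
  nc <- as.integer(strsplit(ln[ic], " +")[[1]][2])
  cel <- matrix(scan(text = ln[(ic + 1):(ic + nc)], quiet = TRUE),
                ncol = 9, byrow = TRUE)[, -1, drop = FALSE] + 1L
  cell_data <- list()
  for (i in grep("^SCALARS ", ln)) {
    nm <- strsplit(ln[i], " +")[[1]][2]
    cell_data[[nm]] <- scan(text = ln[(i + 2):(i + 1 + nc)], quiet = TRUE)
  }
  point_data <- list()
  for (i in grep("^VECTORS ", ln)) {
    nm <- strsplit(ln[i], " +")[[1]][2]
    point_data[[nm]] <- matrix(scan(text = ln[(i + 1):(i + np)], quiet = TRUE),
                               ncol = 3, byrow = TRUE)
  }
  list(points = pts, cells = cel, cell_data = cell_data,
       point_data = point_data)
}
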