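#' Pipeline configuration
#'
#' One config drives the whole paired analysis: specimen generation, micro-CT
#' and CBCT emulation, segmentation, model building, loading and solving.
#' Stage seeds are derived from the master seed by fixed offsets (specimen:
#' +0, micro scan: +1, CBCT scan: +2) and recorded in the run manifest.
#'
#' @param specimen a [specimen_spec()]; its `rng_seed` is overridden by
#'   `seed`.
#' @param micro_scanner,cbct_scanner [scanner_spec()]s (seeds overridden).
#' @param seg_params [graphcut_params()] for the refinement stage.
#' @param denoise_method,denoise_radius_mm denoising applied before
#'   thresholding: a light Gaussian by default — at desk-scale lattices a cube
#'   median filter erases one-voxel trabecular struts.
#' @param n_seeds_per_class seeds per class for the programmatic seeding
#'   protocol ([seeds_from_truth()]).
#' @param min_component_voxels cleanup threshold for [clean_components()].
#' @param materials list with elements `refined` and `simplified`, each a
#'   label -> `c(E, nu)` table (default [material_table()]).
#' @param load_N axial load magnitude per implant (default 50 N).
#' @param per_implant if `TRUE` each implant carries the full `load_N`.
#' @param load_axis unit 3-vector of the implant long axis.
#' @param long_axis specimen long (mesial-distal) axis index.
#' @param tol,maxiter solver controls.
#' @param solver `"pcg"` or `"direct"`.
#' @param seed master RNG seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(specimen = specimen_spec(),
                            micro_scanner = scanner_spec("micro_ct",
                                                         blur_sigma_mm = 0.15,
                                                         noise_sd = 8),
                            cbct_scanner = scanner_spec("cbct",
                                                        blur_sigma_mm = 0.45,
                                                        noise_sd = 5),
                            seg_params = graphcut_params(),
                            denoise_method = "gaussian",
                            denoise_radius_mm = 0.1,
                            n_seeds_per_class = 300L,
                            min_component_voxels = 2L,
                            materials = list(
                              refined = material_table("refined"),
                              simplified = material_table("simplified")),
                            load_N = 50, per_implant = TRUE,
                            load_axis = c(0, 0, 1), long_axis = 1L,
                            tol = 1e-8, maxiter = 20000L,
                            solver = c("pcg", "direct"),
                            seed = 1L) {
  solver <- match.arg(solver)
  seed <- as.integer(seed)
  specimen$rng_seed <- seed
  micro_scanner$rng_seed <- seed + 1L
  cbct_scanner$rng_seed <- seed + 2L
  structure(
    list(specimen = specimen, micro_scanner = micro_scanner,
         cbct_scanner = cbct_scanner, seg_params = seg_params,
         denoise_method = denoise_method,
         denoise_radius_mm = denoise_radius_mm,
         n_seeds_per_class = as.integer(n_seeds_per_class),
         min_component_voxels = as.integer(min_component_voxels),
         materials = materials, load_N = load_N, per_implant = per_implant,
         load_axis = load_axis, long_axis = as.integer(long_axis),
         tol = tol, maxiter = as.integer(maxiter), solver = solver,
         seed = seed),
    class = "pipeline_config"
  )
}

# md5 digest of an arbitrary R object (serialized with fixed version)
object_digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}

solve_branch <- function(labels, config, variant) {
  mesh <- voxels_to_hexmesh(labels)
  mesh <- assign_materials(mesh, config$materials[[variant]])
  bcs <- build_bcs(mesh, load_N = config$load_N, axis = config$load_axis,
                   long_axis = config$long_axis,
                   per_implant = config$per_implant)
  sol <- assemble_and_solve(mesh, bcs, tol = config$tol,
                            maxiter = config$maxiter, method = config$solver)
  strain <- element_strain(mesh, sol)
  stress <- element_stress(strain, mesh)
  interface <- find_interface(mesh)
  summary <- summarize_interface(stress, strain, mesh, interface,
                                 variant = variant)
  list(labels = labels, mesh = mesh, bcs = bcs, solution = sol,
       strain = strain, stress = stress, interface = interface,
       summary = summary)
}

#' Run the refined (microstructural) branch
#'
#' Micro-CT emulation, segmentation (median denoise, two-stage discriminant
#' threshold, programmatically seeded graph-cut refinement, component
#' cleanup), voxel hexahedral meshing with the refined material table (one
#' bone material), and the 50 N axial load solve; returns mesh, fields and
#' the interface summary.
#'
#' @param config a [pipeline_config()].
#' @param truth optionally, a pre-generated ground-truth [label_map()]
#'   (regenerated from the config when omitted).
#' @param bypass_segmentation if `TRUE`, solve directly on the ground-truth
#'   labels, quantifying the segmentation-induced error by comparison.
#' @return a list with `labels`, `mesh`, `bcs`, `solution`, `strain`,
#'   `stress`, `interface`, `summary`, `image`, `truth`.
#' @export
run_refined_branch <- function(config, truth = NULL,
                               bypass_segmentation = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(truth)) truth <- generate_trabecular_specimen(config$specimen)
  micro <- simulate_scan(truth, config$micro_scanner)
  if (bypass_segmentation) {
    labels <- truth
  } else {
    den <- denoise(micro, config$denoise_method,
                   radius_mm = config$denoise_radius_mm)
    init <- threshold_segment(den)
    seeds <- seeds_from_truth(truth, den, config$n_seeds_per_class)
    refined <- graphcut_refine(den, init, seeds, config$seg_params)
    labels <- clean_components(refined, config$min_component_voxels)
  }
  out <- solve_branch(labels, config, "refined")
  out$image <- micro
  out$truth <- truth
  out
}

#' Run the simplified (homogenized) branch
#'
#' The CBCT image is emulated for demonstration, but the solved simplified
#' model derives from the homogenized ground truth (cortical shell +
#' cancellous block + implants) on the same micro lattice as the refined
#' branch, so the paired comparison isolates the effect of microstructure
#' from element-size effects.
#'
#' @inheritParams run_refined_branch
#' @return a list as in [run_refined_branch()], plus `cbct_image` and
#'   `homogenized`.
#' @export
run_simplified_branch <- function(config, truth = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(truth)) truth <- generate_trabecular_specimen(config$specimen)
  homog <- make_homogenized_truth(truth)
  cbct <- simulate_scan(truth, config$cbct_scanner)
  out <- solve_branch(homog, config, "simplified")
  out$cbct_image <- cbct
  out$homogenized <- homog
  out$truth <- truth
  out
}

#' Run the paired refined-vs-simplified comparison
#'
#' Generates one ground truth, runs both branches on it under the identical
#' load, and reports the per-measure percent changes at the implant-bone
#' interface together with a reproducibility manifest (config hash, stage
#' digests, solver reports).
#'
#' @inheritParams run_refined_branch
#' @param out_dir optional directory; when given, volumes, VTK field files,
#'   the comparison TSV and JSON summaries are written there.
#' @return a list of class `perifem_run`: `refined`, `simplified`,
#'   `comparison` (a `comparison_report`), `truth`, `manifest`.
#' @export
run_comparison <- function(config, bypass_segmentation = FALSE,
                           out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- generate_trabecular_specimen(config$specimen)
  refined <- run_refined_branch(config, truth = truth,
                                bypass_segmentation = bypass_segmentation)
  simplified <- run_simplified_branch(config, truth = truth)
  comparison <- compare_models(refined$summary, simplified$summary)
  manifest <- list(
    config_hash = object_digest(config),
    stage_digests = list(
      truth = object_digest(truth$labels),
      micro_image = object_digest(refined$image$values),
      cbct_image = object_digest(simplified$cbct_image$values),
      refined_labels = object_digest(refined$labels$labels),
      refined_summary = object_digest(as.data.frame(refined$summary)),
      simplified_summary = object_digest(as.data.frame(simplified$summary)),
      comparison = object_digest(as.data.frame(comparison))
    ),
    solve_reports = list(refined = refined$solution$report,
                         simplified = simplified$solution$report),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  run <- structure(
    list(refined = refined, simplified = simplified, comparison = comparison,
         truth = truth, manifest = manifest),
    class = "perifem_run"
  )
  if (!is.null(out_dir)) persist_run(run, config, out_dir)
  run
}

persist_run <- function(run, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(run$truth, file.path(out_dir, "truth"))
  write_volume(run$simplified$homogenized, file.path(out_dir, "homogenized"))
  write_volume(run$refined$image, file.path(out_dir, "micro_image"))
  write_volume(run$simplified$cbct_image, file.path(out_dir, "cbct_image"))
  write_volume(run$refined$labels, file.path(out_dir, "refined_labels"))
  for (v in c("refined", "simplified")) {
    br <- run[[v]]
    export_fields(br$mesh, file.path(out_dir, paste0(v, "_fields.vtk")),
                  stress = br$stress, strain = br$strain,
                  solution = br$solution, interface = br$interface)
    jsonlite::write_json(
      tibble::as_tibble(br$summary),
      file.path(out_dir, paste0(v, "_summary.json")),
      auto_unbox = TRUE, digits = NA)
  }
  write_comparison_tsv(run$comparison, file.path(out_dir, "comparison.tsv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.perifem_run <- function(x, ...) {
  cat("<perifem_run>\n")
  print(x$comparison)
  invisible(x)
}

#' @export
tidy.perifem_run <- function(x, ...) tibble::as_tibble(x$comparison)

#' @export
glance.perifem_run <- function(x, ...) glance(x$comparison)
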