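# Orchestration layer: each pipeline_* step writes its outputs plus a JSON
# manifest (inputs, seed, package version, parameter hash) so a run is
# fully reproducible from its output directory.

write_manifest <- function(dir, step, seed, params, inputs = character(0)) {
  manifest <- list(
    step = step,
    seed = seed,
    version = as.character(utils::packageVersion("alpsdti")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = inputs,
    param_hash = rlang::hash(params))
  jsonlite::write_json(manifest,
                       file.path(dir, paste0("manifest_", step, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

check_overwrite <- function(paths, force) {
  existing <- paths[file.exists(paths)]
  if (length(existing) && !force) {
    abort(sprintf("Output already exists (use force = TRUE): %s",
                  paste(existing, collapse = ", ")),
          class = "alps_io_error")
  }
  invisible(paths)
}

#' Generate and write a DWI phantom
#'
#' Writes the simulated 4D DWI (NIfTI + FSL bval/bvec), the matching ROI
#' YAML and the analytic ground truth, plus a manifest.
#'
#' @param out_dir Output directory.
#' @param seed Root seed; the spec's seed is replaced by it.
#' @param spec An `alps_phantom_spec`.
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with the written paths and the phantom.
#' @export
pipeline_phantom <- function(out_dir, seed = 1L, spec = phantom_spec(),
                             force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec$seed <- as.integer(seed)
  paths <- file.path(out_dir, c("dwi.nii.gz", "dwi.bval", "dwi.bvec",
                                "rois.yaml", "ground_truth.csv"))
  names(paths) <- c("nifti", "bval", "bvec", "rois", "truth")
  check_overwrite(paths, force)
  phantom <- make_phantom(spec)
  dwi <- simulate_dwi(phantom)
  write_dwi(dwi, paths["nifti"], paths["bval"], paths["bvec"])
  write_roi_specs(phantom$rois, paths["rois"])
  truth <- purrr::imap_dfr(phantom$tensors, function(tv, comp)
    dplyr::bind_cols(tibble(compartment = comp), as_tibble(t(tv))))
  truth$analytic_alps <- phantom$analytic_alps
  write_results(truth, paths["truth"])
  write_manifest(out_dir, "phantom", seed,
                 params = spec)
  invisible(list(paths = paths, phantom = phantom, dwi = dwi))
}

#' Compute per-subject ALPS indices from DWI files
#'
#' @param out_dir Output directory for `alps.csv` and the manifest.
#' @param nifti_path,bval_path,bvec_path DWI input files.
#' @param roi_path ROI YAML/JSON config.
#' @param subject Subject identifier.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the per-subject `alps_subject` tibble.
#' @export
pipeline_alps <- function(out_dir, nifti_path, bval_path, bvec_path,
                          roi_path, subject = "subject", force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_csv <- file.path(out_dir, "alps.csv")
  check_overwrite(out_csv, force)
  dwi <- read_dwi(nifti_path, bval_path, bvec_path)
  rois <- read_roi_specs(roi_path)
  res <- compute_subject_alps(dwi, rois, subject = subject)
  write_results(res, out_csv)
  write_manifest(out_dir, "alps", seed = NA, params = list(rois = rois),
                 inputs = c(nifti_path, bval_path, bvec_path, roi_path))
  invisible(res)
}

#' Simulate and write a cohort table
#'
#' @param out_dir Output directory for `cohort.csv` and the manifest.
#' @param seed Root seed.
#' @param spec An `alps_cohort_spec`.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the cohort tibble.
#' @export
pipeline_cohort <- function(out_dir, seed = 1L, spec = cohort_spec(),
                            force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_csv <- file.path(out_dir, "cohort.csv")
  check_overwrite(out_csv, force)
  cohort <- simulate_cohort(spec, seed = seed)
  write_results(cohort, out_csv)
  write_manifest(out_dir, "cohort", seed, params = spec)
  invisible(cohort)
}

#' Run the statistics battery on a cohort CSV
#'
#' @param out_dir Output directory for the result CSVs and manifest.
#' @param cohort_path Cohort CSV (schema of [read_cohort()]).
#' @param alpha Significance threshold.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the `alps_group_analysis`.
#' @export
pipeline_stats <- function(out_dir, cohort_path, alpha = 0.05,
                           force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  check_overwrite(file.path(out_dir, "ancova.csv"), force)
  cohort <- read_cohort(cohort_path)
  analysis <- run_group_analysis(cohort, alpha = alpha)
  write_group_analysis(analysis, out_dir)
  write_manifest(out_dir, "stats", seed = NA,
                 params = list(alpha = alpha), inputs = cohort_path)
  invisible(analysis)
}

#' Run the whole pipeline end to end
#'
#' Chains phantom generation, imaging-based ALPS computation, cohort
#' simulation and the statistics battery. One phantom is built per cohort
#' group with its perivascular boost chosen so the analytic ALPS equals
#' the group's mean ALPS; the imaging-derived group ALPS values then
#' replace the cohort spec's ALPS margin means, so the simulated cohort
#' inherits the measured indices.
#'
#' @param out_dir Output directory.
#' @param seed Root seed for every stochastic stage.
#' @param alpha Significance threshold for the statistics stage.
#' @param cohort_spec An `alps_cohort_spec`.
#' @param phantom_spec An `alps_phantom_spec` used as the per-group
#'   template.
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with the per-group ALPS tibble, the cohort
#'   and the analysis.
#' @export
pipeline_full <- function(out_dir, seed = 1L, alpha = 0.05,
                          cohort_spec = alpsdti::cohort_spec(),
                          phantom_spec = alpsdti::phantom_spec(),
                          force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  check_overwrite(file.path(out_dir, c("group_alps.csv", "cohort.csv",
                                       "ancova.csv")), force)
  base_dxx <- phantom_spec$tensors$projection["dxx"]
  group_alps <- purrr::map_dfr(GROUP_LEVELS, function(gname) {
    spec_g <- phantom_spec
    spec_g$seed <- derive_seed(seed, "phantom") + match(gname, GROUP_LEVELS)
    # boost such that (base + delta) / base = target group mean ALPS
    target <- cohort_spec$margins$alps$mean[[gname]]
    spec_g$perivascular_boost <- unname(base_dxx * (target - 1))
    phantom <- make_phantom(spec_g)
    dwi <- simulate_dwi(phantom)
    res <- compute_subject_alps(dwi, phantom$rois, subject = gname)
    res$analytic_alps <- phantom$analytic_alps
    res
  })
  write_results(group_alps, file.path(out_dir, "group_alps.csv"))

  cohort_spec$margins$alps$mean[GROUP_LEVELS] <-
    setNames(group_alps$alps, group_alps$subject)[GROUP_LEVELS]
  cohort <- simulate_cohort(cohort_spec, seed = seed)
  write_results(cohort, file.path(out_dir, "cohort.csv"))
  analysis <- run_group_analysis(cohort, alpha = alpha)
  write_group_analysis(analysis, out_dir)
  write_manifest(out_dir, "full", seed,
                 params = list(cohort = cohort_spec, phantom = phantom_spec,
                               alpha = alpha))
  invisible(list(group_alps = group_alps, cohort = cohort,
                 analysis = analysis))
}
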