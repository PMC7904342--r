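validate_cohort <- function(cohort) {
  missing_cols <- setdiff(COHORT_REQUIRED, names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("Cohort table is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "alps_schema_error")
  }
  num_cols <- setdiff(COHORT_REQUIRED, c("id", "group", "sex"))
  for (cl in num_cols) {
    if (!is.numeric(cohort[[cl]])) {
      abort(sprintf("Cohort column `%s` must be numeric.", cl),
            class = "alps_validation_error")
    }
  }
  if (!all(cohort$group %in% GROUP_LEVELS)) {
    abort(sprintf("Invalid group label(s); allowed: %s.",
                  paste(GROUP_LEVELS, collapse = ", ")),
          class = "alps_validation_error")
  }
  if (!all(cohort$sex %in% c("M", "F"))) {
    abort("Sex must be coded M or F.", class = "alps_validation_error")
  }
  mm <- cohort$mmse[!is.na(cohort$mmse)]
  if (any(mm < 0 | mm > 30)) {
    abort("MMSE must lie in [0, 30].", class = "alps_validation_error")
  }
  hy <- cohort$hy[!is.na(cohort$hy)]
  if (any(!hy %in% HY_LEVELS)) {
    abort("Modified HY stage must be one of 0, 0.5, ..., 5.",
          class = "alps_validation_error")
  }
  dna <- c(cohort$nuclear_dna, cohort$mito_dna)
  if (any(dna < 0, na.rm = TRUE)) {
    abort("Plasma DNA levels must be non-negative.",
          class = "alps_validation_error")
  }
  invisible(cohort)
}

#' Read a cohort table from CSV
#'
#' Expects one row per subject with the columns `id`, `group` (NC, PDN,
#' PD-MCI, PDD), `age`, `sex` (M/F), `disease_duration`, UPDRS subscales
#' (`updrs1`, `updrs2`, `updrs3`, `updrs_total`), `hy`, `se_adl`, `mmse`,
#' `casi`, the five cognitive-domain z-scores (`z_attention`,
#' `z_executive`, `z_language`, `z_memory`, `z_visuospatial`),
#' `nuclear_dna`, `mito_dna` (ng/mL) and `alps`. Unknown columns are
#' preserved but ignored by the analyses.
#'
#' @param path CSV path (UTF-8, header row).
#' @return A validated tibble; `group` becomes a factor with the NC level
#'   first.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path),
                                class = "alps_io_error")
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(cohort)
  cohort$group <- factor(cohort$group, levels = GROUP_LEVELS)
  cohort
}

#' Write a results or cohort table as CSV
#'
#' @param table A data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}
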