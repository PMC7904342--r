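ANCOVA_OUTCOMES <- c("disease_duration", "updrs1", "updrs2", "updrs3",
                     "updrs_total", "hy", "se_adl", "mmse", "casi",
                     DOMAIN_COLS, "nuclear_dna", "mito_dna", "alps")
CORR_ALL_PAIRS <- c("nuclear_dna", "mito_dna", "mmse", "casi")
CORR_PD_PAIRS <- c("updrs2", "updrs3", "updrs_total")

#' Run the full group-comparison and correlation battery
#'
#' Reproduces the standard glymphatic cohort analysis on a cohort table:
#' one-way ANOVA for age; Pearson chi-square for sex by group; ANCOVA
#' (age + sex covariates) with Bonferroni pairwise post hocs for every
#' clinical, cognitive, plasma-DNA and ALPS outcome; an additional ALPS
#' ANCOVA over NC vs early PD (HY <= 2) vs late PD (HY > 2); and Spearman
#' correlations of ALPS with plasma DNA and global cognition across all
#' subjects plus with UPDRS II/III/total within the PD rows.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param alpha Significance threshold carried into the summary; default
#'   0.05.
#' @param outcomes Outcome columns for the ANCOVA family; defaults to all
#'   standard columns present in `cohort`.
#' @return An object of class `alps_group_analysis`: a list of tibbles
#'   (`age_anova`, `sex_chisq`, `ancova`, `posthoc`, `hy_ancova`,
#'   `hy_posthoc`, `correlations`) with [tidy()] and [glance()] methods.
#' @export
run_group_analysis <- function(cohort, alpha = 0.05,
                               outcomes = intersect(ANCOVA_OUTCOMES,
                                                    names(cohort))) {
  validate_cohort(cohort)
  cohort$group <- factor(cohort$group, levels = GROUP_LEVELS)

  age_anova <- anova_oneway(cohort, "age", "group")
  sex_chisq <- chi_square_independence(cohort, "sex", "group")

  fits <- purrr::map(outcomes, function(v) ancova(cohort, v))
  names(fits) <- outcomes
  ancova_tbl <- purrr::map_dfr(fits, function(f)
    new_stat_result("ancova", f$outcome, statistic = f$statistic,
                    df = sprintf("%d, %d", f$df1, f$df2), p = f$p))
  posthoc_tbl <- purrr::map_dfr(fits, bonferroni_posthoc)

  hy_cohort <- hy_split(cohort)
  hy_cohort$hy3 <- factor(
    ifelse(hy_cohort$group == "NC", "NC",
           paste0(hy_cohort$hy_stage_group, " PD")),
    levels = c("NC", "early PD", "late PD"))
  hy_fit <- ancova(hy_cohort, "alps", group = "hy3")
  hy_ancova <- new_stat_result("ancova", "alps (NC/early/late)",
                               statistic = hy_fit$statistic,
                               df = sprintf("%d, %d", hy_fit$df1,
                                            hy_fit$df2),
                               p = hy_fit$p)
  hy_posthoc <- bonferroni_posthoc(hy_fit)

  pd <- cohort[cohort$group != "NC", , drop = FALSE]
  correlations <- dplyr::bind_rows(
    purrr::map_dfr(intersect(CORR_ALL_PAIRS, names(cohort)),
                   function(v) spearman_cor(cohort, "alps", v)),
    purrr::map_dfr(intersect(CORR_PD_PAIRS, names(cohort)),
                   function(v) spearman_cor(pd, "alps", v)))

  structure(list(age_anova = age_anova, sex_chisq = sex_chisq,
                 ancova = ancova_tbl, posthoc = posthoc_tbl,
                 hy_ancova = hy_ancova, hy_posthoc = hy_posthoc,
                 correlations = correlations,
                 fits = fits, hy_fit = hy_fit,
                 alpha = alpha, n = nrow(cohort)),
            class = "alps_group_analysis")
}

#' @export
print.alps_group_analysis <- function(x, ...) {
  td <- tidy(x)
  cat(sprintf("<alps_group_analysis> n = %d subjects, %d tests, %d significant at alpha = %g\n",
              x$n, nrow(td),
              sum(dplyr::coalesce(td$p_adj, td$p) < x$alpha, na.rm = TRUE),
              x$alpha))
  cat("Families: age ANOVA, sex chi-square, ANCOVA (+Bonferroni), HY split, Spearman\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.alps_group_analysis <- function(x, ...) {
  dplyr::bind_rows(x$age_anova, x$sex_chisq, x$ancova, x$posthoc,
                   x$hy_ancova, x$hy_posthoc, x$correlations)
}

#' @exportS3Method generics::glance
glance.alps_group_analysis <- function(x, ...) {
  td <- tidy(x)
  eff <- dplyr::coalesce(td$p_adj, td$p)
  tibble(n_subjects = x$n, n_tests = nrow(td),
         n_significant = sum(eff < x$alpha, na.rm = TRUE),
         alpha = x$alpha)
}

#' Write the analysis bundle as CSV files
#'
#' One CSV per output family, written into `dir`.
#'
#' @param analysis An `alps_group_analysis`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_group_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "alps_group_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- c("age_anova", "sex_chisq", "ancova", "posthoc", "hy_ancova",
           "hy_posthoc", "correlations")
  paths <- vapply(fam, function(f) {
    p <- file.path(dir, paste0(f, ".csv"))
    write_results(analysis[[f]], p)
    p
  }, character(1))
  invisible(paths)
}
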