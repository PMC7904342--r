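#' Cognitive-status classification
#'
#' Movement-disorder-society-style rule set on five cognitive-domain
#' z-scores and the MMSE. A domain is impaired iff its z-score is at or
#' below -1.5 (boundary counts as impaired). PDD requires impairment in
#' more than one domain together with MMSE below 26; otherwise PD-MCI
#' requires impairment in two or more domains; otherwise PDN. Note the
#' literal reading leaves single-domain impairment classified as PDN.
#'
#' @param domain_z Numeric vector of the five domain z-scores (attention,
#'   executive, language, memory, visuospatial) for one subject, or an
#'   n x 5 matrix/data frame for many.
#' @param mmse MMSE score(s), 0-30.
#' @return Character label(s): `"PDN"`, `"PD-MCI"` or `"PDD"`.
#' @examples
#' classify_cognitive_status(c(-2, -2, 0, 0, 0), mmse = 25)  # PDD
#' @export
classify_cognitive_status <- function(domain_z, mmse) {
  if (is.data.frame(domain_z)) domain_z <- as.matrix(domain_z)
  if (is.null(dim(domain_z))) domain_z <- matrix(domain_z, nrow = 1)
  if (ncol(domain_z) != 5 || any(!is.finite(domain_z))) {
    abort("`domain_z` must supply 5 finite z-scores per subject.",
          class = "alps_validation_error")
  }
  n_impaired <- rowSums(domain_z <= -1.5)
  dplyr::case_when(
    n_impaired > 1 & mmse < 26 ~ "PDD",
    n_impaired >= 2 ~ "PD-MCI",
    .default = "PDN")
}

#' Add the classified cognitive status to a cohort table
#'
#' @param cohort Cohort tibble with the five domain z columns and `mmse`.
#' @return The cohort with a `cognitive_status` column (NA for NC rows).
#' @export
add_cognitive_status <- function(cohort) {
  z <- as.matrix(cohort[, DOMAIN_COLS])
  status <- rep(NA_character_, nrow(cohort))
  ok <- rowSums(!is.finite(z)) == 0 & is.finite(cohort$mmse)
  status[ok] <- classify_cognitive_status(z[ok, , drop = FALSE],
                                          cohort$mmse[ok])
  status[cohort$group == "NC"] <- NA_character_
  dplyr::mutate(cohort, cognitive_status = status)
}

#' Early/late disease split by Hoehn-Yahr stage
#'
#' Early PD is modified HY <= 2 (boundary inclusive); late PD is HY > 2.
#'
#' @param cohort Cohort tibble.
#' @return The cohort with an `hy_stage_group` column (`early`/`late` for
#'   PD rows, NA for NC).
#' @export
hy_split <- function(cohort) {
  pd <- cohort$group != "NC"
  if (any(pd & is.na(cohort$hy))) {
    abort("Missing HY stage on a PD row.", class = "alps_validation_error")
  }
  dplyr::mutate(cohort, hy_stage_group = dplyr::case_when(
    .data$group == "NC" ~ NA_character_,
    .data$hy <= 2 ~ "early",
    .default = "late"))
}

new_stat_result <- function(test, variable, statistic, df, p,
                            p_adj = NA_real_, contrast = NA_character_,
                            estimate = NA_real_) {
  tibble(test = test, variable = variable, contrast = contrast,
         estimate = estimate, statistic = statistic, df = df, p = p,
         p_adj = p_adj)
}

drop_missing <- function(data, cols, label) {
  keep <- stats::complete.cases(data[, cols])
  if (any(!keep)) {
    inform(sprintf("%s: dropped %d row(s) with missing values.",
                   label, sum(!keep)))
  }
  data[keep, , drop = FALSE]
}

#' One-way ANOVA
#'
#' @param data Data frame.
#' @param value Name of the numeric outcome column.
#' @param group Name of the grouping column (>= 2 groups, each n >= 2).
#' @return One-row `StatResult` tibble: F statistic, `df` as
#'   `"k-1, N-k"`, and the F-distribution p-value.
#' @export
anova_oneway <- function(data, value, group = "group") {
  data <- drop_missing(as.data.frame(data)[, c(value, group)],
                       c(value, group), "ANOVA")
  g <- droplevels(factor(data[[group]]))
  y <- data[[value]]
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("ANOVA needs >= 2 groups with n >= 2 each.",
          class = "alps_validation_error")
  }
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  Fv <- s$`F value`[1]
  p <- s$`Pr(>F)`[1]
  if (stats::var(y) == 0 || is.nan(Fv)) { Fv <- 0; p <- 1 }  # no variation

  new_stat_result("anova", value, statistic = Fv,
                  df = sprintf("%d, %d", s$Df[1], s$Df[2]), p = p)
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction, matching the classic Pearson statistic
#' `sum((O - E)^2 / E)` on an r x c contingency table.
#'
#' @param x A contingency matrix of non-negative counts, or a data frame
#'   whose columns `row_var` and `col_var` are cross-tabulated first.
#' @param row_var,col_var Column names used when `x` is a data frame.
#' @return One-row `StatResult` tibble.
#' @export
chi_square_independence <- function(x, row_var = NULL, col_var = NULL) {
  if (is.data.frame(x)) {
    x <- drop_missing(x, c(row_var, col_var), "chi-square")
    tab <- table(x[[row_var]], x[[col_var]])
    label <- paste(row_var, "x", col_var)
  } else {
    tab <- as.table(as.matrix(x))
    label <- "table"
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Contingency table has a zero margin.",
          class = "alps_validation_error")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  new_stat_result("chi_square", label, statistic = unname(ct$statistic),
                  df = as.character(unname(ct$parameter)),
                  p = ct$p.value)
}

#' ANCOVA with age and sex covariates
#'
#' Fits `outcome ~ group + age + sex` (no interactions) and tests the
#' group factor by the extra-sum-of-squares F against the
#' covariates-only model (Type II). Covariate-adjusted group means are
#' estimated at the covariate means (proportional weighting over sex).
#'
#' @param data Data frame containing the outcome, `group` and the
#'   covariates; rows with missing values in any of these are dropped
#'   with a message.
#' @param outcome Name of the numeric outcome column.
#' @param group Name of the grouping factor.
#' @param covariates Character vector of covariate columns.
#' @return An object of class `alps_ancova` with the lm fit, the group F
#'   test and adjusted means; see [tidy()]/[glance()] methods and
#'   [bonferroni_posthoc()].
#' @export
ancova <- function(data, outcome, group = "group",
                   covariates = c("age", "sex")) {
  cols <- c(outcome, group, covariates)
  data <- drop_missing(as.data.frame(data)[, cols], cols,
                       paste("ANCOVA", outcome))
  data[[group]] <- droplevels(factor(data[[group]]))
  if (nlevels(data[[group]]) < 2) {
    abort("ANCOVA needs >= 2 groups after dropping missing rows.",
          class = "alps_validation_error")
  }
  for (cv in covariates) {
    if (is.character(data[[cv]])) data[[cv]] <- factor(data[[cv]])
  }
  # degenerate covariates (a single level / zero variance) are dropped so
  # the design stays full rank; the group test then reduces to one-way ANOVA
  keep_cov <- covariates[vapply(covariates, function(cv) {
    v <- data[[cv]]
    if (is.factor(v)) nlevels(droplevels(v)) > 1 else stats::var(v) > 0
  }, logical(1))]
  rhs_red <- if (length(keep_cov)) paste(keep_cov, collapse = " + ") else "1"
  full <- lm(stats::reformulate(c(group, keep_cov), response = outcome),
             data = data)
  if (any(is.na(coef(full)))) {
    abort(sprintf("Collinear ANCOVA design for `%s`.", outcome),
          class = "alps_estimation_error")
  }
  reduced <- lm(stats::reformulate(rhs_red, response = outcome), data = data)
  cmp <- anova(reduced, full)
  Fv <- cmp$F[2]
  p <- cmp$`Pr(>F)`[2]
  df1 <- cmp$Df[2]
  df2 <- full$df.residual
  if (is.nan(Fv)) { Fv <- 0; p <- 1 }
  structure(list(fit = full, reduced = reduced, outcome = outcome,
                 group = group, covariates = keep_cov, data = data,
                 statistic = Fv, df1 = df1, df2 = df2, p = p),
            class = "alps_ancova")
}

# Covariate-adjusted means, computed on demand (proportional weighting
# over factor covariates, i.e. estimation at the covariate means).
ancova_emmeans <- function(x) {
  emmeans::emmeans(x$fit, x$group, weights = "proportional")
}

#' @export
print.alps_ancova <- function(x, ...) {
  cat(sprintf("<alps_ancova> %s ~ %s + %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$outcome, x$group,
              paste(x$covariates, collapse = " + "),
              x$df1, x$df2, x$statistic, x$p))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.alps_ancova <- function(x, ...) {
  tibble(outcome = x$outcome, statistic = x$statistic, df1 = x$df1,
         df2 = x$df2, p.value = x$p,
         r.squared = summary(x$fit)$r.squared, nobs = nrow(x$data))
}

#' @exportS3Method generics::tidy
tidy.alps_ancova <- function(x, ...) {
  adj <- as_tibble(as.data.frame(ancova_emmeans(x)))
  names(adj)[1] <- "group"
  dplyr::rename(adj, adjusted_mean = "emmean")
}

#' Bonferroni-corrected pairwise post hoc contrasts
#'
#' All pairwise covariate-adjusted group contrasts from a fitted ANCOVA,
#' tested by t statistics with `p_adj = min(1, m * p)` where `m` is the
#' number of pairs in the family (6 for four groups).
#'
#' @param fit An `alps_ancova`.
#' @return `StatResult` tibble with one row per pair.
#' @export
bonferroni_posthoc <- function(fit) {
  stopifnot(inherits(fit, "alps_ancova"))
  ctr <- as.data.frame(emmeans::contrast(ancova_emmeans(fit),
                                         method = "pairwise",
                                         adjust = "none"))
  m <- nrow(ctr)
  new_stat_result("ancova_posthoc", fit$outcome,
                  contrast = as.character(ctr$contrast),
                  estimate = ctr$estimate,
                  statistic = ctr$t.ratio,
                  df = as.character(ctr$df),
                  p = ctr$p.value,
                  p_adj = pmin(1, m * ctr$p.value))
}

#' Spearman rank correlation
#'
#' Rho computed on average ranks (ties averaged); p-value from the t
#' approximation with n - 2 degrees of freedom, or from the exact
#' permutation null for small samples when `exact = TRUE`.
#'
#' @param data Data frame.
#' @param x,y Names of the two numeric columns.
#' @param exact Use the exact permutation distribution (only for n <= 10).
#' @return One-row `StatResult` tibble with `statistic` = rho.
#' @export
spearman_cor <- function(data, x, y, exact = FALSE) {
  data <- drop_missing(as.data.frame(data)[, c(x, y)], c(x, y),
                       paste0("Spearman ", x, " ~ ", y))
  xv <- data[[x]]; yv <- data[[y]]
  n <- length(xv)
  if (n < 3) abort("Spearman correlation needs n >= 3.",
                   class = "alps_validation_error")
  rx <- rank(xv); ry <- rank(yv)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("Zero variance in ranks.", class = "alps_validation_error")
  }
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 10) abort("Exact permutation mode is limited to n <= 10.",
                      class = "alps_validation_error")
    perms <- permutations(n)
    rho_null <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  new_stat_result("spearman", paste0(x, " ~ ", y), statistic = rho,
                  df = as.character(n - 2L), p = p)
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
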