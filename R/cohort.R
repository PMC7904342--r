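# Copula margins are transformed per group; bounds keep physical ranges
# (DNA >= 0, MMSE in [0, 30], SE-ADL/CASI in [0, 100], HY in [0, 5]) via
# monotone truncated-normal quantile maps, so latent rank correlations
# survive the truncation exactly.
COPULA_VARS <- c("age", "disease_duration", "updrs1", "updrs2", "updrs3",
                 "updrs_total", "hy", "se_adl", "mmse", "casi", DOMAIN_COLS,
                 "nuclear_dna", "mito_dna", "alps")
PD_ONLY_VARS <- c("disease_duration", "updrs1", "updrs2", "updrs3",
                  "updrs_total", "hy", "se_adl")

default_margins <- function() {
  g <- function(nc, pdn, mci, pdd) c(NC = nc, PDN = pdn, `PD-MCI` = mci,
                                     PDD = pdd)
  list(
    age = list(mean = g(61.53, 60.08, 63.80, 65.76),
               sd = g(4.75, 10.07, 8.70, 8.00)),
    disease_duration = list(mean = g(NA, 2.49, 3.07, 3.64),
                            sd = g(NA, 1.91, 2.67, 4.28), lower = 0),
    updrs1 = list(mean = g(NA, 3.16, 3.76, 3.76),
                  sd = g(NA, 2.29, 3.00, 3.07), lower = 0),
    updrs2 = list(mean = g(NA, 8.40, 9.48, 11.55),
                  sd = g(NA, 6.31, 7.50, 8.17), lower = 0),
    updrs3 = list(mean = g(NA, 19.56, 24.76, 27.47),
                  sd = g(NA, 13.14, 15.41, 14.47), lower = 0),
    updrs_total = list(mean = g(NA, 31.12, 38.00, 42.79),
                       sd = g(NA, 20.26, 24.25, 23.98), lower = 0),
    hy = list(mean = g(NA, 1.86, 2.16, 1.88),
              sd = g(NA, 1.25, 1.26, 0.84), lower = 0, upper = 5,
              round_to = 0.5),
    se_adl = list(mean = g(NA, 83.60, 82.00, 85.26),
                  sd = g(NA, 20.99, 22.55, 11.32), lower = 0, upper = 100),
    mmse = list(mean = g(27.21, 27.92, 27.08, 20.00),
                sd = g(2.06, 1.78, 1.32, 4.53), lower = 0, upper = 30),
    casi = list(mean = g(88.76, 92.87, 86.62, 69.62),
                sd = g(6.47, 3.80, 7.79, 15.66), lower = 0, upper = 100),
    z_attention = list(mean = g(0, 0, -1.8, -2.2), sd = g(1, 0.8, 0.6, 0.7)),
    z_executive = list(mean = g(0, 0, -1.8, -2.2), sd = g(1, 0.8, 0.6, 0.7)),
    z_language = list(mean = g(0, 0, -0.8, -2.0), sd = g(1, 0.8, 0.6, 0.7)),
    z_memory = list(mean = g(0, 0, -0.8, -2.2), sd = g(1, 0.8, 0.6, 0.7)),
    z_visuospatial = list(mean = g(0, 0, -0.8, -2.0),
                          sd = g(1, 0.8, 0.6, 0.7)),
    nuclear_dna = list(mean = g(19.34, 31.35, 32.03, 46.13),
                       sd = g(14.76, 26.18, 21.40, 33.67), lower = 0),
    mito_dna = list(mean = g(31.54, 39.89, 45.36, 43.04),
                    sd = g(33.86, 31.04, 38.70, 31.17), lower = 0),
    alps = list(mean = g(1.52, 1.48, 1.42, 1.38),
                sd = g(0.12, 0.12, 0.12, 0.12), lower = 0))
}

#' Specify a simulated four-group cohort
#'
#' Encodes the study design the statistics battery expects: group sizes,
#' sex ratios and per-group marginal means/SDs for demographics, disease
#' severity, cognition, plasma DNA and the ALPS index, plus target
#' Spearman correlations between ALPS and selected variables. Defaults
#' reproduce the published group summaries (n = 47/25/25/38; nuclear DNA
#' 19.34/31.35/32.03/46.13 ng/mL, and so on) with rank-correlation targets
#' rho(ALPS, nuclear DNA) = -0.278, rho(ALPS, mito DNA) = -0.201,
#' rho(ALPS, MMSE) = 0.222, rho(ALPS, CASI) = 0.178 and
#' rho(ALPS, UPDRS II/III/total) = -0.238/-0.331/-0.307.
#'
#' @param n Named integer vector of group sizes (NC, PDN, PD-MCI, PDD),
#'   each >= 2.
#' @param male_frac Named numeric vector of male proportions per group.
#' @param margins Named list of per-variable lists with `mean` and `sd`
#'   (named by group) and optional `lower`, `upper`, `round_to`.
#' @param rho_alps Named target Spearman correlations between `alps` and
#'   other margin variables, each in (-1, 1).
#' @param seed Integer root seed.
#' @return A list of class `alps_cohort_spec`.
#' @export
cohort_spec <- function(n = c(NC = 47, PDN = 25, `PD-MCI` = 25, PDD = 38),
                        male_frac = c(NC = 15 / 47, PDN = 15 / 25,
                                      `PD-MCI` = 8 / 25, PDD = 11 / 38),
                        margins = default_margins(),
                        rho_alps = c(nuclear_dna = -0.278, mito_dna = -0.201,
                                     mmse = 0.222, casi = 0.178,
                                     updrs2 = -0.238, updrs3 = -0.331,
                                     updrs_total = -0.307),
                        seed = 1L) {
  if (!all(GROUP_LEVELS %in% names(n)) || any(n < 2)) {
    abort("`n` must name all four groups with n >= 2 each.",
          class = "alps_validation_error")
  }
  if (any(abs(rho_alps) >= 1)) {
    abort("Target Spearman correlations must lie in (-1, 1).",
          class = "alps_validation_error")
  }
  bad <- setdiff(names(rho_alps), setdiff(COPULA_VARS, "alps"))
  if (length(bad)) {
    abort(sprintf("Unknown correlation target(s): %s.",
                  paste(bad, collapse = ", ")),
          class = "alps_validation_error")
  }
  for (v in names(margins)) {
    if (any(margins[[v]]$sd < 0, na.rm = TRUE)) {
      abort(sprintf("Margin `%s` has a negative SD.", v),
            class = "alps_validation_error")
    }
  }
  spec <- structure(list(n = n[GROUP_LEVELS], male_frac = male_frac,
                         margins = margins, rho_alps = rho_alps,
                         seed = as.integer(seed)),
                    class = "alps_cohort_spec")
  latent_correlation(spec)  # fail early if not positive definite
  spec
}

# Latent Gaussian correlation matrix from the Spearman targets:
# r = 2 sin(pi * rho / 6) is exact for the Gaussian copula.
latent_correlation <- function(spec) {
  p <- length(COPULA_VARS)
  R <- diag(p)
  dimnames(R) <- list(COPULA_VARS, COPULA_VARS)
  for (v in names(spec$rho_alps)) {
    r <- 2 * sin(pi * spec$rho_alps[[v]] / 6)
    R["alps", v] <- R[v, "alps"] <- r
  }
  ok <- tryCatch({chol(R); TRUE}, error = function(e) FALSE)
  if (!ok) {
    abort("Target correlation matrix is not positive definite.",
          class = "alps_validation_error")
  }
  R
}

#' Simulate a cohort table
#'
#' Draws per-subject rows from a Gaussian copula with the spec's target
#' rank-correlation structure and per-group marginal means/SDs. Bounded
#' margins use monotone truncated-normal quantile transforms (so rank
#' correlations are preserved); HY stages are rounded to half steps; sex
#' is Bernoulli per group ratio; disease variables are `NA` for NC. Group
#' labels come from the generating group and the domain z-score means are
#' chosen so [classify_cognitive_status()] reproduces the label at the
#' group mean.
#'
#' @param spec An `alps_cohort_spec`.
#' @param seed Optional override of the spec seed.
#' @return A validated cohort tibble (one row per subject).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "alps_cohort_spec"))
  seed <- seed %||% spec$seed
  R <- latent_correlation(spec)
  L <- chol(R)
  with_seed(derive_seed(seed, "cohort"), {
    rows <- purrr::map(GROUP_LEVELS, function(gname) {
      ng <- spec$n[[gname]]
      Z <- matrix(rnorm(ng * ncol(R)), ng) %*% L
      colnames(Z) <- COPULA_VARS
      out <- tibble(group = gname,
                    sex = ifelse(runif(ng) < spec$male_frac[[gname]],
                                 "M", "F"))
      for (v in COPULA_VARS) {
        m <- spec$margins[[v]]
        if (gname == "NC" && v %in% PD_ONLY_VARS) {
          out[[v]] <- NA_real_
          next
        }
        val <- truncnorm_transform(Z[, v], m$mean[[gname]], m$sd[[gname]],
                                   lower = m$lower %||% -Inf,
                                   upper = m$upper %||% Inf)
        if (!is.null(m$round_to)) {
          val <- pmin(pmax(round(val / m$round_to) * m$round_to,
                           m$lower %||% -Inf), m$upper %||% Inf)
        }
        out[[v]] <- val
      }
      out
    })
    cohort <- dplyr::bind_rows(rows)
    cohort <- dplyr::mutate(
      cohort,
      id = sprintf("S%03d", dplyr::row_number()),
      group = factor(.data$group, levels = GROUP_LEVELS),
      .before = 1)
    validate_cohort(cohort)
    cohort
  })
}
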