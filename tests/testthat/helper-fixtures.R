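# Shared fixtures, all generated in code.

small_phantom_spec <- function(...) {
  phantom_spec(dims = c(12, 12, 10), ...)
}

# Fixed 12-row toy dataset for the ANCOVA oracle check: 3 groups x 4
# subjects, an age trend and unbalanced sex.
ancova_fixture <- function() {
  data.frame(
    y = c(10.2, 11.5, 9.8, 10.9, 13.1, 12.4, 14.0, 13.3,
          15.9, 16.4, 15.1, 17.0),
    group = rep(c("A", "B", "C"), each = 4),
    age = c(61, 64, 58, 70, 66, 59, 72, 63, 68, 61, 74, 65),
    sex = c("M", "F", "F", "M", "F", "F", "M", "F", "M", "M", "F", "F"),
    stringsAsFactors = FALSE)
}

# Minimal valid cohort rows for schema tests.
toy_cohort <- function(n_per_group = 3) {
  spec <- cohort_spec(n = c(NC = n_per_group, PDN = n_per_group,
                            `PD-MCI` = n_per_group, PDD = n_per_group))
  simulate_cohort(spec, seed = 42)
}
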