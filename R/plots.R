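#' ALPS index by group
#'
#' Box-and-jitter plot of the ALPS index across the four cohort groups
#' (or any grouping column), the usual presentation of group differences
#' in glymphatic cohort studies.
#'
#' @param cohort Cohort tibble with `alps` and the grouping column.
#' @param group Grouping column name.
#' @return A ggplot object.
#' @export
plot_alps_by_group <- function(cohort, group = "group") {
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data[[group]], y = .data$alps,
                               fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "ALPS index") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' ALPS correlation panels
#'
#' Scatter plots of the ALPS index against selected variables with a
#' linear trend, faceted per variable.
#'
#' @param cohort Cohort tibble.
#' @param vars Variables to plot against `alps`.
#' @return A ggplot object.
#' @export
plot_alps_correlations <- function(cohort,
                                   vars = c("nuclear_dna", "mito_dna",
                                            "mmse", "casi")) {
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, "alps", dplyr::all_of(vars)),
    -"alps", names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$alps)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "ALPS index") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a tensor-field map
#'
#' @param object An `alps_tensor_field`.
#' @param map One of `fa`, `md`, `dxx`, `dyy`, `dzz`.
#' @param slice Axial (z) slice index; default the middle slice.
#' @param ... Unused.
#' @return A ggplot raster of the requested map.
#' @exportS3Method ggplot2::autoplot
autoplot.alps_tensor_field <- function(object, map = "fa", slice = NULL,
                                       ...) {
  dims <- dim(object$mask)
  slice <- slice %||% ceiling(dims[3] / 2)
  m <- object$maps[[map]][, , slice]
  df <- tidyr::expand_grid(i = seq_len(dims[1]), j = seq_len(dims[2]))
  df$value <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = map) +
    ggplot2::labs(x = "x (voxel)", y = "y (voxel)",
                  title = sprintf("%s, axial slice %d", toupper(map),
                                  slice)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
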