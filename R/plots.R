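#' Plot a Provar profile
#'
#' Per-residue pocket-lining probability in residue order, with the
#' first/third-quartile colour limits drawn as reference lines.
#'
#' @param object A `provar_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.provar_profile <- function(object, ...) {
  df <- tibble::tibble(residue = seq_len(nrow(object)),
                       probability = object$probability)
  lim <- scale_limits(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue,
                                   y = .data$probability)) +
    ggplot2::geom_col(fill = "firebrick", width = 1) +
    ggplot2::geom_hline(yintercept = lim, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "residue (structure order)",
                  y = "pocket-lining probability",
                  title = "Per-residue pocket-lining propensity") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Persistence bar chart
#'
#' Fraction of conformers in which each labelled site occurs.
#'
#' @param persistence Persistence table from [track_ensemble()].
#' @return A ggplot object.
#' @export
plot_persistence <- function(persistence) {
  ggplot2::ggplot(persistence,
                  ggplot2::aes(x = .data$label, y = .data$persistence)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "site", y = "fraction of conformers",
                  title = "Site persistence across the ensemble") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Boxplots of per-site property distributions
#'
#' One panel per property, one box per labelled site, built from the
#' per-conformer values collected by [property_distributions()].
#'
#' @param distributions Output of [property_distributions()].
#' @return A ggplot object.
#' @export
plot_property_distributions <- function(distributions) {
  long <- tidyr::unnest_longer(
    distributions[, c("label", "property", "values")], "values")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$values)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = "site", y = "value",
                  title = "Per-site property distributions") +
    ggplot2::theme_minimal()
}
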