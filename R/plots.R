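#' Plot a metaprofile
#'
#' Line plot of the normalized insertion density against signed distance from
#' the anchor; for TSS/TTS profiles the genic (positive-axis) and intergenic
#' (negative-axis) components are drawn as separate series.
#'
#' @param object A `te_metaprofile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_metaprofile
#' @export
autoplot.te_metaprofile <- function(object, ...) {
  anchor <- attr(object, "anchor") %||% "anchor"
  if ("value" %in% names(object)) {
    df <- tibble(position = object$position, density = object$value,
                 component = "all")
  } else {
    df <- tidyr::pivot_longer(as_tibble(object), c("genic", "intergenic"),
                              names_to = "component", values_to = "density")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$density,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = sprintf("signed distance from %s (bp)", anchor),
      y = "insertions per window per 1e5 insertions per 1e4 anchors",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.te_metaprofile
#' @param x A `te_metaprofile`.
#' @param y Unused.
#' @method plot te_metaprofile
#' @export
plot.te_metaprofile <- function(x, y, ...) print(autoplot(x, ...))

#' Plot an expression-bin targeting curve
#'
#' Mean per-bin percentage of TSS-associated insertions across datasets, with
#' one-standard-deviation error bars; a flat line at `100 / n_bins` percent is
#' the random expectation.
#'
#' @param object A `te_bin_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_bin_curve
#' @export
autoplot.te_bin_curve <- function(object, ...) {
  n_bins <- nrow(object)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin, y = .data$mean_pct)) +
    ggplot2::geom_hline(yintercept = 100 / n_bins, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pct - .data$sd_pct,
                                        ymax = .data$mean_pct + .data$sd_pct),
                           width = 0.3, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "expression bin (1 = lowest)",
                  y = "% of TSS-associated insertions") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.te_bin_curve
#' @param x A `te_bin_curve`.
#' @param y Unused.
#' @method plot te_bin_curve
#' @export
plot.te_bin_curve <- function(x, y, ...) print(autoplot(x, ...))
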