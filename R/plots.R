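#' Plot the health-literacy level distribution
#'
#' @param scored Tibble from [score_hls()].
#' @param type `"d"` or `"p"`.
#' @param weights Weight column name.
#' @return A ggplot object.
#' @export
plot_level_distribution <- function(scored, type = c("d", "p"),
                                    weights = NULL) {
  type <- match.arg(type)
  tb <- level_distribution(scored, type, weights)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$level, y = .data$percent,
                                   fill = .data$level)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of respondents",
                  title = paste0("Health-literacy levels (type ",
                                 toupper(type), ")")) +
    ggplot2::theme_minimal()
}

#' Plot per-item difficulty shares
#'
#' @param tbl Tibble from [item_difficulty_table()].
#' @return A ggplot object.
#' @export
plot_item_difficulty <- function(tbl) {
  tbl$item <- factor(tbl$item, levels = tbl$item)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$item, y = .data$pct_difficult,
                                    group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = '% "difficult" or "very difficult"') +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Graphical model test plot
#'
#' Item difficulties of the two groups against the identity line, with 95%
#' confidence radii; clear departures flag DIF items.
#'
#' @param object `hls_graphical_test` from [graphical_test_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hls_graphical_test <- function(object, ...) {
  tb <- object$items
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$beta_1, y = .data$beta_2)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_2 - .data$radius,
                                        ymax = .data$beta_2 + .data$radius),
                           width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$item), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = paste("difficulty,", object$groups[1]),
                  y = paste("difficulty,", object$groups[2]),
                  title = "Graphical model test") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Empirical vs model item characteristic curves
#'
#' @param object `hls_graphical_test`.
#' @param items Optional subset of items to show.
#' @return A ggplot object.
#' @export
plot_icc <- function(object, items = NULL) {
  tb <- object$icc
  if (!is.null(items)) tb <- tb[tb$item %in% items, ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$raw_score)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed, size = .data$n),
                        alpha = 0.6) +
    ggplot2::facet_wrap(~item) +
    ggplot2::scale_size_area(max_size = 2, guide = "none") +
    ggplot2::labs(x = "raw score", y = "P(response = 1)",
                  title = "Observed vs model ICCs") +
    ggplot2::theme_minimal()
}

#' DIF magnitudes from a facets analysis
#'
#' @param object `hls_dif_facets` from [dif_facets_pcm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hls_dif_facets <- function(object, ...) {
  tb <- object$dif
  tb$item <- factor(tb$item, levels = tb$item)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$item, y = .data$tau_1,
                                   colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$tau_1 - 1.96 * .data$se,
                                          ymax = .data$tau_1 + 1.96 * .data$se)) +
    ggplot2::labs(x = NULL, y = "DIF magnitude (logits, group 1 half)",
                  colour = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
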