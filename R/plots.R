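#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a species-by-language incidence matrix
#'
#' @param object A [build_incidence()] result.
#' @param ... Unused.
#' @return A ggplot tile plot (species x language presence/absence).
#' @export
autoplot.qs_incidence <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(qs_languages()),
                        names_to = "language", values_to = "present")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$language, levels = qs_languages()),
    y = .data$species_id, fill = factor(.data$present))) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "#2166ac"),
                               labels = c(`0` = "absent", `1` = "present"),
                               name = NULL) +
    ggplot2::labs(x = "QS language", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation metrics per classifier
#'
#' Fold means with confidence intervals for accuracy, precision, recall
#' and F1.
#'
#' @param object A [crossvalidate()] result.
#' @param ... Passed to [tidy.qs_cv()] (e.g. `conf_level`).
#' @return A ggplot point-range plot faceted by metric.
#' @export
autoplot.qs_cv <- function(object, ...) {
  td <- tidy(object, ...)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$classifier, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "5-fold CV metric") +
    ggplot2::theme_minimal()
}

#' Plot an RMT threshold scan
#'
#' Fitted Brody beta against the correlation cutoff, with the Poisson
#' acceptance level and the chosen threshold marked.
#'
#' @param object A [rmt_threshold()] result.
#' @param ... Unused.
#' @return A ggplot line plot.
#' @export
autoplot.qs_rmt <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$cutoff, y = .data$beta)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$beta_poisson_tol,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "#b2182b") +
    ggplot2::labs(x = "correlation cutoff", y = "fitted Brody beta") +
    ggplot2::theme_minimal()
}

#' Plot explanation labels of co-occurrence edges
#'
#' @param object An [explain_edges()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of edge counts per explanation label.
#' @export
autoplot.qs_explained <- function(object, ...) {
  counts <- attr(object, "counts")
  df <- tibble(label = names(counts), n = as.integer(counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "co-occurrence edges") +
    ggplot2::theme_minimal()
}
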