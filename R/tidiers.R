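#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a catalog summary
#'
#' @param x A [qs_summarize()] result.
#' @param ... Unused.
#' @return `tidy()`: per-language synthase counts; `glance()`: a one-row
#'   tibble of the headline totals.
#' @export
tidy.qs_summary <- function(x, ...) {
  tibble(language = names(x$per_language_synthase),
         n_synthase = as.integer(x$per_language_synthase))
}

#' @rdname tidy.qs_summary
#' @export
glance.qs_summary <- function(x, ...) {
  tibble(n_entries = x$n_entries, n_total = x$n_total,
         n_synthase = x$n_synthase, n_receptor = x$n_receptor,
         n_species = x$n_species, n_qsb = x$n_qsb,
         qsb_percent = x$qsb_percent)
}

#' Tidy cross-validation results
#'
#' @param x A [crossvalidate()] result.
#' @param conf_level Confidence level for the fold-mean interval
#'   (mean +/- t-quantile * sd / sqrt(k)).
#' @param ... Unused.
#' @return `tidy()`: one row per classifier and metric with `mean`,
#'   `conf_low`, `conf_high`; `glance()`: one row per classifier with the
#'   mean of each metric.
#' @export
tidy.qs_cv <- function(x, conf_level = 0.95, ...) {
  k <- attr(x, "k")
  tq <- qt(1 - (1 - conf_level) / 2, df = k - 1)
  as_tibble(x) |>
    tidyr::pivot_longer(c("accuracy", "precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$classifier, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     conf_low = mean(.data$value) - tq * sd(.data$value) / sqrt(k),
                     conf_high = mean(.data$value) + tq * sd(.data$value) / sqrt(k),
                     .groups = "drop")
}

#' @rdname tidy.qs_cv
#' @export
glance.qs_cv <- function(x, ...) {
  as_tibble(x) |>
    dplyr::group_by(.data$classifier) |>
    dplyr::summarise(dplyr::across(c("accuracy", "precision", "recall", "f1"),
                                   mean), .groups = "drop")
}

#' Tidy a Nemenyi selection
#'
#' @param x A [nemenyi_select()] result.
#' @param ... Unused.
#' @return `tidy()`: the pairwise rank-difference table; `glance()`: a
#'   one-row tibble with the Friedman statistic, p-value, critical
#'   difference and number of selected classifiers.
#' @export
tidy.qs_selection <- function(x, ...) x$pairs

#' @rdname tidy.qs_selection
#' @export
glance.qs_selection <- function(x, ...) {
  tibble(friedman_stat = x$friedman_stat, friedman_p = x$friedman_p,
         friedman_significant = x$friedman_significant, cd = x$cd,
         n_selected = length(x$selected),
         selected = paste(x$selected, collapse = ","))
}

#' Tidy an RMT threshold scan
#'
#' @param x A [rmt_threshold()] result.
#' @param ... Unused.
#' @return `tidy()`: the cutoff scan tibble; `glance()`: one row with the
#'   chosen threshold and convergence flag.
#' @export
tidy.qs_rmt <- function(x, ...) x$scan

#' @rdname tidy.qs_rmt
#' @export
glance.qs_rmt <- function(x, ...) {
  tibble(threshold = x$threshold, converged = x$converged,
         beta_poisson_tol = x$beta_poisson_tol)
}

#' Summarise explained co-occurrence edges
#'
#' @param x An [explain_edges()] result.
#' @param ... Unused.
#' @return One row with the count of each explanation label (no-data edges
#'   excluded) and the total.
#' @export
glance.qs_explained <- function(x, ...) {
  counts <- attr(x, "counts")
  dplyr::bind_cols(as_tibble(as.list(counts)),
                   tibble(total = sum(counts)))
}
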