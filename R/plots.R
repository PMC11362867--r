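#' Plot the linchpin score distribution
#'
#' Histogram of scores with the top-fraction flagging threshold marked,
#' when the table has been through [flag_linchpins()].
#'
#' @param object A `psnet_linchpin` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psnet_linchpin
#' @export
autoplot.psnet_linchpin <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::labs(
      x = "Linchpin score",
      y = "Physicians",
      title = sprintf("Linchpin scores (%s)",
                      paste(attr(object, "specialty") %||% "all",
                            collapse = "/"))
    ) +
    ggplot2::theme_minimal()
  thr <- attr(object, "threshold")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Forest plot of the fitted delay odds ratios
#'
#' Exposure odds ratios with Wald 95% intervals on a log scale; the
#' vertical line marks the null.
#'
#' @param object A `psnet_fit`.
#' @param terms Regular expression selecting terms to show; defaults to
#'   the two exposures.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psnet_fit
#' @export
autoplot.psnet_fit <- function(object,
                               terms = "^linchpin_exposed|^care_density_level",
                               ...) {
  d <- dplyr::filter(tidy(object), grepl(terms, .data$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio,
                                  y = stats::reorder(.data$term,
                                                     .data$odds_ratio))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("Odds ratio of delay (> %g days), 95%% CI", object$cutoff),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of the cohort exclusion flow
#'
#' @param flags Output of [apply_cohort_filters()].
#' @return A ggplot.
#' @export
plot_exclusion_flow <- function(flags) {
  flow <- exclusion_flow(flags)
  ggplot2::ggplot(flow, ggplot2::aes(x = .data$n,
                                     y = .data$exclusion_reason)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Patients", y = NULL,
                  title = "Cohort cascade: first failing rule per patient") +
    ggplot2::theme_minimal()
}
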