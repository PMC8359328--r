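#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot item discrimination estimates of a fit
#'
#' For two-dimensional fits, plots the speed slopes against the ability slopes
#' (one point per item); for one-dimensional fits, the slope estimates by
#' item.
#'
#' @param object a `dsrt_fit`.
#' @param ... unused.
#' @export
autoplot.dsrt_fit <- function(object, ...) {
  it <- object$items
  if (all(c("alpha1", "alpha2") %in% names(it))) {
    ggplot2::ggplot(it, ggplot2::aes(x = .data$alpha1, y = .data$alpha2)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "ability slope", y = "speed slope",
                    title = sprintf("Item discriminations (%s)", object$model))
  } else {
    slope_col <- intersect(c("alpha", "a1", "alpha_acc", "delta"), names(it))[1L]
    ggplot2::ggplot(it, ggplot2::aes(x = .data$item, y = .data[[slope_col]])) +
      ggplot2::geom_point() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
      ggplot2::labs(x = NULL, y = slope_col,
                    title = sprintf("Item parameter estimates (%s)", object$model))
  }
}

#' Plot the predictive distribution of the eigenvalue check
#'
#' Histogram of the bootstrap replicates with the 95% interval and the
#' observed statistic marked.
#'
#' @param object a `dsrt_ppc` from [ppc_eigen()].
#' @param ... unused.
#' @export
autoplot.dsrt_ppc <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$replicates),
                  ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$interval, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "first eigenvalue of RT correlation matrix",
                  y = "bootstrap replicates",
                  title = "Parametric-bootstrap predictive check")
}

#' Shrinkage plot: average ability estimate against the truth
#'
#' The per-person average EAP estimate across replications plotted against the
#' true ability, panelled by model — deviations from the identity line show
#' shrinkage and, under a misspecified model, systematic bias.
#'
#' @param object a `dsrt_condition` or `dsrt_study`.
#' @param ... unused.
#' @export
autoplot.dsrt_condition <- function(object, ...) {
  ggplot2::ggplot(object$per_person,
                  ggplot2::aes(x = .data$truth, y = .data$mean_estimate)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "true ability", y = "average EAP estimate")
}

#' @rdname autoplot.dsrt_condition
#' @export
autoplot.dsrt_study <- function(object, ...) {
  ggplot2::ggplot(object$per_person,
                  ggplot2::aes(x = .data$truth, y = .data$mean_estimate)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_grid(n_items + rho ~ model) +
    ggplot2::labs(x = "true ability", y = "average EAP estimate")
}
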