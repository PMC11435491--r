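#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a composite potency scale
#'
#' Scatter of the two log10 references with the fitted Passing-Bablok line,
#' the orthogonal projections and segments linking each chemical to its
#' projection.
#'
#' @param object A `composite_scale`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composite_scale <- function(object, ...) {
  ch <- object$chemicals[object$chemicals$complete, ]
  unit <- if (object$basis == "mass") "ug/cm2" else "umol/cm2"
  ggplot2::ggplot(ch, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = object$fit$slope,
                         intercept = object$fit$intercept,
                         linetype = "dashed") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x_hat,
                                       yend = .data$y_hat),
                          colour = "grey60") +
    ggplot2::geom_point(size = 2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(x = .data$x_hat, y = .data$y_hat),
                        shape = 3) +
    ggplot2::labs(
      x = paste0("log10 human NOEL (", unit, ")"),
      y = paste0("log10 LLNA NESIL (", unit, ")"),
      title = "Composite potency scale",
      subtitle = sprintf("Passing-Bablok: y = %.3f x + %.3f",
                         object$fit$slope, object$fit$intercept)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a potency model over its training data
#'
#' Log-log scatter of the training data with the fitted prediction line.
#'
#' @param object A `potency_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.potency_model <- function(object, ...) {
  d <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = object$coefficients[["slope"]],
                         intercept = object$coefficients[["intercept"]],
                         linetype = "dashed") +
    ggplot2::geom_point(size = 2, colour = "grey40") +
    ggplot2::labs(
      x = "log10 cDV0", y = "log10 potency",
      title = sprintf("Potency model (%s, %s)", object$family,
                      if (object$with_slope) "intercept + slope"
                      else "intercept only"),
      subtitle = sprintf("log10 potency = %.3f + %.3f log10 cDV0",
                         object$coefficients[["intercept"]],
                         object$coefficients[["slope"]])
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-repeat cross-validation errors
#'
#' Distribution of the per-repeat fold-change errors against each reference.
#'
#' @param object A `potency_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.potency_cv <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_repeat,
                           cols = c("error_vs_llna", "error_vs_noel"),
                           names_to = "reference", values_to = "error")
  d$reference <- ifelse(d$reference == "error_vs_llna",
                        "vs LLNA NESIL", "vs human NOEL")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reference, y = .data$error)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = 1) +
    ggplot2::labs(
      x = NULL, y = "fold-change error (per repeat)",
      title = sprintf("Repeated cross-validation (%d x %d)",
                      object$config$repeats, object$config$folds)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-chemical prediction fold changes
#'
#' One bar per chemical and reference on a log axis, with horizontal lines at
#' the category thresholds.
#'
#' @param categories A `fold_change_categories` object.
#' @return A ggplot object.
#' @export
plot_fold_change_categories <- function(categories) {
  tb <- categories$table
  err_cols <- setdiff(names(tb), c("name", "max_error", "min_error",
                                   "category"))
  d <- tidyr::pivot_longer(tb[, c("name", err_cols)], cols = -"name",
                           names_to = "reference", values_to = "error")
  d <- d[!is.na(d$error), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$name, y = .data$error,
                                  fill = .data$reference)) +
    ggplot2::geom_col(position = "dodge", colour = "grey30") +
    ggplot2::geom_hline(yintercept = categories$within,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = categories$beyond,
                        linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_grey(start = 0.2, end = 0.95) +
    ggplot2::labs(x = NULL, y = "fold-change error") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
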