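# ggplot2 displays for each result type.

#' Plot the brevity/accuracy frontier
#'
#' One point per candidate model (worst-dimension validation R-squared
#' against retained-item count), with the per-count best candidates joined by
#' a line.
#'
#' @param object A `facsimile_frontier` from [run_search()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.facsimile_frontier <- function(object, ...) {
  curve <- frontier_curve(object)
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$n_included, y = .data$r2_min)
  ) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$r2), colour = "#2c7fb8") +
    ggplot2::labs(
      x = "Items included",
      y = expression("Minimum validation" ~ R^2),
      title = "Brevity/accuracy frontier"
    ) +
    ggplot2::theme_minimal()
}

#' Observed versus predicted scores
#'
#' Scatter of held-out observed scores against model predictions, one panel
#' per target dimension, with the identity line for reference.
#'
#' @param object A `facsimile_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.facsimile_eval <- function(object, ...) {
  preds <- attr(object, "predictions")
  ggplot2::ggplot(preds, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.5) +
    ggplot2::facet_wrap(~dimension, scales = "free") +
    ggplot2::labs(x = "Observed score", y = "Predicted score") +
    ggplot2::theme_minimal()
}

#' Sample-size sensitivity curves
#'
#' Mean held-out R-squared by training sample size, one line per retained-item
#' count, with the 95% percentile band.
#'
#' @param object A `sample_size_curve` from [sample_size_curve()].
#' @param n_included Optional subset of retained-item counts to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_size_curve <- function(object, n_included = NULL, ...) {
  dat <- tibble::as_tibble(object)
  if (!is.null(n_included)) {
    dat <- dplyr::filter(dat, .data$n_included %in% !!n_included)
  }
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$sample_size, y = .data$mean_r2,
    group = factor(.data$n_included), colour = factor(.data$n_included),
    fill = factor(.data$n_included)
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Training sample size", y = expression("Held-out" ~ R^2),
      colour = "Items", fill = "Items"
    ) +
    ggplot2::theme_minimal()
}

#' Scree plot
#'
#' Eigenvalues of the item correlation matrix in decreasing order, with the
#' unit line used by the eigenvalue-greater-than-one retention rule.
#'
#' @param efa An `efa_fit`, or a numeric vector of eigenvalues.
#' @return A ggplot object.
#' @export
plot_scree <- function(efa) {
  ev <- if (inherits(efa, "efa_fit")) efa$eigenvalues else as.numeric(efa)
  dat <- tibble::tibble(component = seq_along(ev), eigenvalue = ev)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Component", y = "Eigenvalue", title = "Scree plot") +
    ggplot2::theme_minimal()
}

#' @rdname plot_scree
#' @param object An `efa_fit`.
#' @param ... Unused.
#' @export
autoplot.efa_fit <- function(object, ...) plot_scree(object)
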