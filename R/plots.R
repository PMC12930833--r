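# ggplot2 front-ends for the result types. Figures mirror the standard
# conformal-prediction diagnostics: calibration curve, label distribution
# across significance levels, and the per-case p-value plane.

#' @export
autoplot.cp_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$eps, y = .data$error)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "significance level", y = "observed error rate",
      title = "Conformal calibration"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cp_label_distribution <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$eps, y = .data$fraction, colour = .data$cardinality)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "significance level", y = "fraction of predictions",
      colour = NULL, title = "Prediction-set label distribution"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tcp_result <- function(object, eps = NULL, ...) {
  positive <- attr(object, "positive") %||% "positive"
  df <- mutate(as_tibble(object),
    class = ifelse(.data$truth, positive, paste0("not-", positive))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$p_neg, y = .data$p_pos, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("p-value (not-%s)", positive),
      y = sprintf("p-value (%s)", positive),
      colour = "true class", title = "Transductive conformal p-values"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(eps)) {
    p <- p +
      ggplot2::geom_hline(yintercept = eps, linetype = "dotted") +
      ggplot2::geom_vline(xintercept = eps, linetype = "dotted")
  }
  p
}

#' PLS-DA score plot
#'
#' Projects samples onto the first two PLS components of a fitted model.
#'
#' @param model A `plsda_model`.
#' @param x Predictor matrix used for the projection.
#' @param truth Optional logical positive-class indicator for colouring.
#' @return A ggplot object.
#' @export
plot_plsda_scores <- function(model, x, truth = NULL) {
  core <- model$core
  xs <- sweep(sweep(as.matrix(x)[, model$predictors[core$keep], drop = FALSE],
    2, core$x_center
  ), 2, core$x_scale, "/")
  rot <- core$W %*% solve(crossprod(core$P, core$W))
  scores <- xs %*% rot
  df <- tibble(
    comp1 = scores[, 1],
    comp2 = if (ncol(scores) >= 2) scores[, 2] else 0,
    class = if (is.null(truth)) "sample" else ifelse(truth, model$positive, paste0("not-", model$positive))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comp1, y = .data$comp2, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "component 1", y = "component 2", colour = NULL,
                  title = "PLS-DA scores") +
    ggplot2::theme_minimal()
}
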