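#' Plot per-wedge B-factors and relative scales against nominal dose
#'
#' The conventional decay plot: B-factors as solid lines (left axis,
#' squared angstroms) and relative scales, normalized to their maximum over
#' the wedges, as dashed lines (right axis), both against nominal dose in
#' MGy.
#'
#' @param object A [scale_wedge_series()] result (optionally with a
#'   `sample` column for faceting, as produced by binding several series).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wedge_scales
#' @export
autoplot.wedge_scales <- function(object, ...) {
  df <- tibble::as_tibble(object)
  b_span <- max(df$b, 1e-9)
  df$k_scaled <- df$k / max(df$k) * b_span
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$nominal_dose)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$b, linetype = "B-factor")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$b)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$k_scaled,
                                    linetype = "relative scale")) +
    ggplot2::scale_linetype_manual(
      values = c("B-factor" = "solid", "relative scale" = "dashed"),
      name = NULL) +
    ggplot2::scale_y_continuous(
      name = expression(B ~ (ring(A)^2)),
      sec.axis = ggplot2::sec_axis(~ . / b_span,
                                   name = "relative scale")) +
    ggplot2::labs(x = "nominal dose (MGy)") +
    ggplot2::theme_minimal()
  if ("sample" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~sample, scales = "free")
  }
  p
}

#' @rdname autoplot.wedge_scales
#' @export
plot.wedge_scales <- function(x, ...) print(autoplot.wedge_scales(x, ...))

#' Plot a fitted decay line over the B-versus-dose series
#'
#' @param object A [fit_beta()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nominal_dose, y = .data$b)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$beta) +
    ggplot2::labs(
      x = "nominal dose (MGy)", y = expression(B ~ (ring(A)^2)),
      subtitle = sprintf("beta = %.3f ± %.3f Å²/MGy (r² = %.3f)",
                         object$beta, object$se_beta, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.decay_fit
#' @export
plot.decay_fit <- function(x, ...) print(autoplot.decay_fit(x, ...))
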