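# Plotting -------------------------------------------------------------------

#' Plot a rate estimate
#'
#' Inferred rate values (crosses) over the observed regulator states, with
#' the observation probability `P(x2)` as a shaded band along the baseline
#' and, optionally, the true rate as a dashed line. States flagged
#' unreliable (never observed; values interpolated by the smoothness
#' penalty alone) are drawn hollow.
#'
#' @param object A `rate_estimate`.
#' @param true_rate Optional true rate (function, `hill_params`, or tibble
#'   with `x2`, `f`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_estimate <- function(object, true_rate = NULL, ...) {
  d <- object$estimate
  ymax <- max(d$f)
  d$p_scaled <- d$p_x2 / max(d$p_x2, 1e-300) * 0.25 * ymax
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x2)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$p_scaled), fill = "grey80",
                       alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$f, alpha = .data$reliable),
                        shape = 4, colour = "darkorange", stroke = 1.1) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "x2 (regulator abundance)",
                  y = if (object$scale_known) "f(x2)" else "tau3 * f(x2)") +
    ggplot2::theme_minimal()
  if (!is.null(true_rate)) {
    ft <- tibble(x2 = d$x2, f = true_rate_values(true_rate, d$x2))
    p <- p + ggplot2::geom_line(data = ft, ggplot2::aes(y = .data$f),
                                linetype = "dashed", colour = "steelblue")
  }
  p
}

#' Plot the conditional-mean baseline against a rate estimate
#'
#' Compares the naive conditional average `<x3 | x2> / tau3` (grey line),
#' which identifies the rate only when the regulator fluctuates slowly,
#' with the flux-balance estimate.
#'
#' @param estimate A `rate_estimate`.
#' @param samples The `snapshot_ensemble` behind it.
#' @param tau3 Downstream lifetime used to scale the conditional mean.
#' @param true_rate Optional true rate overlay.
#' @return A ggplot object.
#' @export
plot_conditional_baseline <- function(estimate, samples, tau3 = 1,
                                      true_rate = NULL) {
  cm <- conditional_mean(samples)
  p <- autoplot(estimate, true_rate = true_rate) +
    ggplot2::geom_line(data = tibble(x2 = cm$x2, f = cm$mean / tau3),
                       ggplot2::aes(y = .data$f), colour = "grey40")
  p
}
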