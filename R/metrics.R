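# Inference-quality metrics --------------------------------------------------

#' Probability-weighted inference error
#'
#' Error heuristic
#' `E = sum_x2 |f_inferred(x2) - f_true(x2)| * P(x2) / <f_true>`, with
#' `<f_true> = sum_x2 f_true(x2) P(x2)`: deviations are weighted by how
#' often the state was actually observed and normalized by the mean true
#' rate, so `E` is dimensionless. States never observed carry zero weight
#' and drop out automatically.
#'
#' @param estimate A `rate_estimate` (or a tibble with columns `x2`, `f`).
#' @param f_true True rate: a function of `x2`, a `hill_params` object, or a
#'   tibble with columns `x2`, `f`.
#' @param p_x2 Optional probability weights over the estimate's `x2` states;
#'   defaults to the weights stored in the estimate.
#' @return An `error_report`: list with `E`, `mean_true_rate` and the
#'   `per_state` tibble (`x2`, `f_inferred`, `f_true`, `abs_error`, `p`).
#' @examples
#' # doubling the rate everywhere gives E = 1 regardless of the weights
#' est <- tibble::tibble(x2 = 0:5, f = 2 * (0:5 + 1))
#' inference_error(est, function(x) x + 1, p_x2 = rep(1 / 6, 6))$E
#' @export
inference_error <- function(estimate, f_true, p_x2 = NULL) {
  if (inherits(estimate, "rate_estimate")) {
    tab <- estimate$estimate
    if (is.null(p_x2)) p_x2 <- tab$p_x2
  } else {
    tab <- as_tibble(estimate)
    if (is.null(p_x2)) abort("`p_x2` is required when `estimate` is a plain table.")
  }
  if (length(p_x2) != nrow(tab)) abort("`p_x2` must match the estimate support.")
  p <- p_x2 / sum(p_x2)
  ft <- true_rate_values(f_true, tab$x2)
  mean_true <- sum(ft * p)
  if (mean_true <= 0) abort("mean true rate is zero; E is undefined.")
  abs_err <- abs(tab$f - ft)
  structure(list(E = sum(abs_err * p) / mean_true,
                 mean_true_rate = mean_true,
                 per_state = tibble(x2 = tab$x2, f_inferred = tab$f,
                                    f_true = ft, abs_error = abs_err, p = p)),
            class = "error_report")
}

true_rate_values <- function(f_true, x2) {
  if (inherits(f_true, "hill_params")) return(hill_rate(f_true)(x2))
  if (is.function(f_true)) return(f_true(x2))
  tab <- as_tibble(f_true)
  if (!all(c("x2", "f") %in% names(tab)))
    abort("`f_true` table must have columns x2 and f.")
  m <- match(x2, tab$x2)
  if (anyNA(m)) abort("`f_true` is not evaluable on every x2 state of the estimate.")
  tab$f[m]
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> E = %.4g (mean true rate %.4g over %d states)\n",
              x$E, x$mean_true_rate, nrow(x$per_state)))
  invisible(x)
}

#' @export
tidy.error_report <- function(x, ...) x$per_state

#' @export
glance.error_report <- function(x, ...) {
  tibble(E = x$E, mean_true_rate = x$mean_true_rate,
         n_states = nrow(x$per_state))
}

#' Upstream importance from the noise-propagation relation
#'
#' For any system in which the regulated component is produced at rate
#' `f(x2)` and degraded in first order, the stationary moments satisfy
#' `Var(x3)/<x3>^2 = 1/<x3> + Cov(x3, f(x2)) / (<x3> <f>)`. The importance
#' `I = |eta_x3f| / eta_x3x3` is the fraction of the squared coefficient of
#' variation of `x3` attributable to covariation with the regulator; small
#' `I` predicts poor inferability. `I` is invariant to the overall scale of
#' `f`, so an inferred shape (`tau3 * f`) can be used when the scale is
#' unknown. The residual of the relation itself is reported as a
#' self-consistency diagnostic (it converges to zero for linear degradation
#' as sampling grows, and is not expected to vanish otherwise).
#'
#' @param samples A `snapshot_ensemble`.
#' @param f Rate: function, `hill_params`, `rate_estimate`, or tibble
#'   (`x2`, `f`).
#' @return An `importance_report`: list with `eta_x3x3` (squared CV of x3),
#'   `eta_x3f` (normalized covariance), `I`, and `flux_residual`.
#' @export
importance <- function(samples, f) {
  x3 <- samples$x3
  if (var(x3) == 0) abort("x3 is degenerate; importance is undefined.")
  fvals <- if (inherits(f, "rate_estimate")) rate_function(f)(samples$x2)
           else true_rate_values(f, samples$x2)
  m3 <- mean(x3)
  mf <- mean(fvals)
  # plain (biased) sample moments: N is large in all intended uses
  n <- length(x3)
  v3 <- mean((x3 - m3)^2)
  cf <- mean((x3 - m3) * (fvals - mf))
  eta33 <- v3 / m3^2
  eta3f <- if (mf > 0) cf / (m3 * mf) else 0
  structure(list(eta_x3x3 = eta33, eta_x3f = eta3f,
                 I = abs(eta3f) / eta33,
                 flux_residual = eta33 - 1 / m3 - eta3f,
                 n = n),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> I = %.4g (eta_x3x3 = %.4g, eta_x3f = %.4g, flux residual = %.3g)\n",
              x$I, x$eta_x3x3, x$eta_x3f, x$flux_residual))
  invisible(x)
}

#' @export
glance.importance_report <- function(x, ...) {
  tibble(I = x$I, eta_x3x3 = x$eta_x3x3, eta_x3f = x$eta_x3f,
         flux_residual = x$flux_residual, n = x$n)
}
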