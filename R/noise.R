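# Measurement-noise models ---------------------------------------------------
#
# Three corruption models for snapshot ensembles: additive Gaussian noise
# (absolute error in molecules), multiplicative Gaussian noise (relative
# error), and binomial undercounting (each molecule detected with
# probability p). Gaussian noise is applied independently per coordinate
# (the minimal reading of a "two-dimensional" error with no stated
# cross-correlation), values are rounded to the nearest integer because the
# balance equations live on discrete states, and measurements driven
# negative are discarded with the ensemble renormalized; the discard count
# is recorded in the metadata.

#' Corrupt snapshots with additive Gaussian measurement noise
#'
#' @param samples A `snapshot_ensemble`.
#' @param sigma_abs Standard deviation in molecules, `>= 0`.
#' @param seed Integer seed.
#' @return A corrupted `snapshot_ensemble`; `attr(, "meta")$n_discarded`
#'   counts measurements dropped for turning negative.
#' @export
apply_additive <- function(samples, sigma_abs, seed = NULL) {
  stopifnot(sigma_abs >= 0)
  if (sigma_abs == 0) return(samples)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(samples)
  x2 <- round(samples$x2 + rnorm(n, 0, sigma_abs))
  x3 <- round(samples$x3 + rnorm(n, 0, sigma_abs))
  keep_positive(x2, x3, samples, kind = "additive",
                params = list(sigma_abs = sigma_abs, seed = seed))
}

#' Corrupt snapshots with relative (multiplicative) Gaussian noise
#'
#' Each coordinate is multiplied by an independent Normal(1, `sigma_rel`)
#' draw.
#'
#' @param samples A `snapshot_ensemble`.
#' @param sigma_rel Relative standard deviation, `>= 0`.
#' @param seed Integer seed.
#' @return A corrupted `snapshot_ensemble` (see [apply_additive()]).
#' @export
apply_relative <- function(samples, sigma_rel, seed = NULL) {
  stopifnot(sigma_rel >= 0)
  if (sigma_rel == 0) return(samples)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(samples)
  x2 <- round(samples$x2 * rnorm(n, 1, sigma_rel))
  x3 <- round(samples$x3 * rnorm(n, 1, sigma_rel))
  keep_positive(x2, x3, samples, kind = "relative",
                params = list(sigma_rel = sigma_rel, seed = seed))
}

keep_positive <- function(x2, x3, samples, kind, params) {
  keep <- x2 >= 0 & x3 >= 0
  if (!any(keep))
    abort("all measurements were discarded as negative; noise level too large.")
  meta <- attr(samples, "meta") %||% list()
  meta$noise <- c(list(kind = kind), params)
  meta$n_discarded <- sum(!keep)
  new_snapshot_ensemble(x2[keep], x3[keep], meta = meta)
}

#' Corrupt snapshots with binomial undercounting
#'
#' Each molecule is detected independently with probability `p_detect`:
#' every coordinate is replaced by a Binomial(value, `p_detect`) draw.
#' Always non-negative; no measurements are discarded.
#'
#' @param samples A `snapshot_ensemble`.
#' @param p_detect Detection probability in `(0, 1]`.
#' @param seed Integer seed.
#' @return A corrupted `snapshot_ensemble`.
#' @export
apply_undercount <- function(samples, p_detect, seed = NULL) {
  check_p(p_detect)
  if (p_detect == 1) return(samples)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(samples)
  meta <- attr(samples, "meta") %||% list()
  meta$noise <- list(kind = "undercount", p_detect = p_detect, seed = seed)
  new_snapshot_ensemble(rbinom(n, samples$x2, p_detect),
                        rbinom(n, samples$x3, p_detect), meta = meta)
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1)
    abort("`p_detect` must be in (0, 1].")
}

#' Correct binomial undercounting by rescaling
#'
#' Undercounting with known detection probability `p` is undone by
#' multiplying measured molecule numbers by `1/p`.
#'
#' For a `snapshot_ensemble` or `joint_distribution`, the regulator axis is
#' rescaled: `x2` states map to `round(x2 / p)` (probabilities of colliding
#' states are merged). This recovers the correct rate *shape* over the true
#' `x2` scale. For a `rate_estimate`, the axis map is applied and the rate
#' values are additionally multiplied by `1/p`: when the regulated
#' coordinate was undercounted too, binomial thinning of its birth-death
#' makes the apparent production rate `p * f`, so the full correction is
#' `f(x2) = f_measured(p x2) / p`. With `p` unknown the shape is still
#' identified, but not the scale of the `x2` axis.
#'
#' @param x A `snapshot_ensemble`, `joint_distribution`, or `rate_estimate`.
#' @param p_detect Detection probability in `(0, 1]`.
#' @return Corrected object of the same class.
#' @export
correct_undercount <- function(x, p_detect) UseMethod("correct_undercount")

#' @export
correct_undercount.snapshot_ensemble <- function(x, p_detect) {
  check_p(p_detect)
  if (p_detect == 1) return(x)
  meta <- attr(x, "meta") %||% list()
  meta$undercount_corrected <- p_detect
  new_snapshot_ensemble(round(x$x2 / p_detect), x$x3, meta = meta)
}

#' @export
correct_undercount.joint_distribution <- function(x, p_detect) {
  check_p(p_detect)
  if (p_detect == 1) return(x)
  new_x2 <- as.integer(round(x$x2 / p_detect))
  lv <- seq(min(new_x2), max(new_x2))
  prob <- matrix(0, length(lv), length(x$x3))
  for (j in seq_along(new_x2)) { # merge colliding states
    r <- match(new_x2[j], lv)
    prob[r, ] <- prob[r, ] + x$prob[j, ]
  }
  joint_distribution(lv, x$x3, prob, n_source_samples = x$n_source_samples)
}

#' @export
correct_undercount.rate_estimate <- function(x, p_detect) {
  check_p(p_detect)
  if (p_detect == 1) return(x)
  new_x2 <- as.integer(round(x$estimate$x2 / p_detect))
  dup <- !duplicated(new_x2)
  out <- x
  out$estimate <- tibble(x2 = new_x2[dup],
                         f = x$estimate$f[dup] / p_detect,
                         p_x2 = vapply(new_x2[dup], function(v)
                           sum(x$estimate$p_x2[new_x2 == v]), numeric(1)),
                         reliable = x$estimate$reliable[dup])
  out
}
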