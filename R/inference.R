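# Flux-balance inversion ----------------------------------------------------
#
# At stationarity, the probability flux crossing any abundance cut of the
# regulated component upward (production, +1 per event) must equal the flux
# crossing it downward (degradation). For first-order decay x3/tau3 the cut
# between levels m and m+1 gives
#     sum_j P(x2 = j, x3 = m) f(j)  =  (m + 1) P(x3 = m + 1) / tau3,
# and for dimer decay gamma x3 (x3 - 1) removing two molecules the downward
# flux collects the two states whose jump crosses the cut:
#     sum_j P(x2 = j, x3 = m) f(j)
#       = gamma (m+1) m P(m+1) + gamma (m+2)(m+1) P(m+2).
# Stacking the cuts yields G f = h with G_mj = P(x2 = j, x3 = m). The rate
# vector f over observed x2 states is recovered by a non-negative least
# squares solve with a second-difference (discrete curvature) penalty.

#' Assemble the flux-balance linear system
#'
#' Builds `G`, `h` from an observed joint distribution and a degradation
#' specification. Rows correspond to cuts at the observed `x3` levels
#' `m = min .. max - step`; the top `step` cuts are dropped because their
#' downward flux references levels beyond the observed range (truncation
#' makes those rows inconsistent by construction).
#'
#' @param joint A `joint_distribution`.
#' @param degradation A [degradation_spec()].
#' @return A `balance_system`: matrix `G` (cuts x x2-states), vector `h`,
#'   `x2_states`, `x3_cuts`, the `x2` marginal `px2`, sample size `n`, and
#'   the degradation spec.
#' @export
assemble_balance_system <- function(joint, degradation) {
  if (!inherits(joint, "joint_distribution")) abort("`joint` must be a joint_distribution.")
  if (!inherits(degradation, "degradation_spec")) abort("`degradation` must be a degradation_spec.")
  d <- degradation$step
  lv <- joint$x3
  if (length(lv) <= d)
    abort("joint distribution has too few x3 levels for this degradation step.")
  cuts <- lv[seq_len(length(lv) - d)]
  G <- t(joint$prob[, seq_along(cuts), drop = FALSE])
  p3 <- colSums(joint$prob)
  h <- vapply(cuts, function(m) {
    s <- seq_len(d)
    sum(degradation$g(m + s) * p3[match(m + s, lv)])
  }, numeric(1))
  structure(list(G = G, h = h, x2_states = joint$x2, x3_cuts = cuts,
                 px2 = rowSums(joint$prob), n = joint$n_source_samples,
                 degradation = degradation),
            class = "balance_system")
}

#' @export
print.balance_system <- function(x, ...) {
  cat(sprintf("<balance_system> %d cut equations, %d x2 states (%s degradation)\n",
              length(x$h), length(x$x2_states), x$degradation$kind))
  invisible(x)
}

#' Default regularization strength
#'
#' The curvature penalty must weaken as sampling improves; the default
#' heuristic is `1 / sqrt(N)` (rule `"inverse_sqrt_n"`), with `1 / N`
#' (`"inverse_n"`) available as an alternative. The package-wide default
#' rule can be set via `options(ratesnap.epsilon_rule = ...)`.
#'
#' The `1 / sqrt(N)` default matches the scale of the sampling error: the
#' entries of an empirical joint distribution fluctuate around the true
#' probabilities with standard deviation `O(1 / sqrt(N))`, so a penalty of
#' that order suppresses noise-driven curvature without biasing resolvable
#' structure. `1 / N` decays too fast in practice and lets the estimate
#' overfit multinomial noise at moderate `N`.
#'
#' @param n_samples Number of snapshots behind the joint distribution.
#' @param rule `"inverse_sqrt_n"` or `"inverse_n"`.
#' @return Positive regularization strength, strictly decreasing in `n_samples`.
#' @export
default_epsilon <- function(n_samples,
                            rule = getOption("ratesnap.epsilon_rule",
                                             "inverse_sqrt_n")) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1)
    abort("`n_samples` must be a single value >= 1.")
  rule <- match.arg(rule, c("inverse_sqrt_n", "inverse_n"))
  if (rule == "inverse_n") 1 / n_samples else 1 / sqrt(n_samples)
}

# (n-2) x n second-difference matrix
second_difference_matrix <- function(n) {
  if (n < 3) return(matrix(0, 0, n))
  i <- rep(seq_len(n - 2), each = 3)
  j <- as.vector(vapply(seq_len(n - 2), function(r) r + 0:2, numeric(3)))
  x <- rep(c(1, -2, 1), n - 2)
  M <- matrix(0, n - 2, n)
  M[cbind(i, j)] <- x
  M
}

#' Infer the production rate function from a balance system
#'
#' Solves the convex program
#' `min_f || G f - h ||^2 + epsilon || D2 f ||^2  s.t.  f >= 0`
#' (with `D2` the second-difference matrix) via non-negative least squares;
#' convexity guarantees the global optimum. Optional monotonicity constraints
#' are imposed by a cumulative-sum reparameterization that keeps the problem
#' an NNLS.
#'
#' @param balance A `balance_system` from [assemble_balance_system()].
#' @param epsilon Regularization strength `>= 0`; default [default_epsilon()]
#'   of the sample size behind the joint (1 if the joint is exact).
#' @param constraint `"none"`, `"increasing"` or `"decreasing"` monotonicity
#'   of the recovered rate.
#' @return A `rate_estimate`: tibble accessor via [tidy()], with columns
#'   `x2`, `f` (the rate; `tau3 * f` when the degradation scale is unknown),
#'   `p_x2` (observation probability of the state) and `reliable`
#'   (`FALSE` for interior states never observed, whose values come from the
#'   smoothness penalty alone). Attributes carry `epsilon`, the objective
#'   value, the model label and the degradation spec.
#' @export
infer_rate <- function(balance, epsilon = NULL,
                       constraint = c("none", "increasing", "decreasing")) {
  constraint <- match.arg(constraint)
  if (is.null(epsilon))
    epsilon <- if (balance$n >= 1) default_epsilon(balance$n) else
      default_epsilon(1e6)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0)
    abort("`epsilon` must be a single non-negative number.")
  G <- balance$G
  h <- balance$h
  n <- ncol(G)
  D2 <- second_difference_matrix(n)
  A <- rbind(G, sqrt(epsilon) * D2)
  b <- c(h, rep(0, nrow(D2)))
  Tm <- switch(constraint,
    none = diag(n),
    increasing = lower.tri(matrix(0, n, n), diag = TRUE) * 1,
    decreasing = upper.tri(matrix(0, n, n), diag = TRUE) * 1
  )
  sol <- tryCatch(pracma::lsqnonneg(A %*% Tm, b),
                  error = function(e)
                    abort(paste0("NNLS solver failed: ", conditionMessage(e))))
  f <- as.vector(Tm %*% sol$x)
  f[f < 0] <- 0 # guard against roundoff
  objective <- sum((G %*% f - h)^2) + epsilon * sum((D2 %*% f)^2)
  new_rate_estimate(
    x2 = balance$x2_states, f = f, px2 = balance$px2,
    epsilon = epsilon, model = "free", objective = objective,
    constraint = constraint, degradation = balance$degradation,
    n = balance$n
  )
}

new_rate_estimate <- function(x2, f, px2, epsilon, model, objective,
                              constraint = "none", degradation = NULL,
                              n = 0, cv = NULL) {
  est <- tibble(x2 = as.integer(x2), f = as.numeric(f),
                p_x2 = as.numeric(px2), reliable = px2 > 0)
  structure(list(estimate = est, epsilon = epsilon, model = model,
                 objective = objective, constraint = constraint,
                 degradation = degradation,
                 scale_known = degradation$scale_known %||% TRUE,
                 n = n, cv = cv),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  lab <- if (x$scale_known) "f(x2)" else "tau3 * f(x2) (scale unknown)"
  cat(sprintf("<rate_estimate> %s over %d x2 states; model = %s, epsilon = %.3g, objective = %.4g\n",
              lab, nrow(x$estimate), x$model, x$epsilon %||% NA_real_,
              x$objective))
  if (!is.null(x$cv))
    cat(sprintf("  cross-validation: err_const = %.4g, err_free = %.4g (margin %.0f%%)\n",
                x$cv$err_const, x$cv$err_free, 100 * (x$cv$margin - 1)))
  invisible(x)
}

#' @export
tidy.rate_estimate <- function(x, ...) x$estimate

#' @export
glance.rate_estimate <- function(x, ...) {
  tibble(model = x$model, epsilon = x$epsilon %||% NA_real_,
         objective = x$objective, n_states = nrow(x$estimate),
         n_samples = x$n, scale_known = x$scale_known)
}

#' Evaluate a rate estimate as a function
#'
#' Returns a function over non-negative integers: exact table lookup on the
#' estimated support, constant continuation below/beyond it (the only
#' assumption-free extension).
#'
#' @param estimate A `rate_estimate`.
#' @return A vectorized function.
#' @export
rate_function <- function(estimate) {
  x2 <- estimate$estimate$x2
  f <- estimate$estimate$f
  function(x) {
    # nearest-neighbour lookup (supports may be non-contiguous, e.g. after
    # an undercounting axis correction); edges continue as constants
    xi <- pmin(pmax(round(x), min(x2)), max(x2))
    lo <- findInterval(xi, x2)
    hi <- pmin(lo + 1L, length(x2))
    lo <- pmax(lo, 1L)
    use_hi <- abs(x2[hi] - xi) < abs(xi - x2[lo])
    f[ifelse(use_hi, hi, lo)]
  }
}

#' Best-fitting constant production rate
#'
#' One-parameter least squares `lambda * (G 1) ~ h` with `lambda >= 0`; the
#' reduced model of the cross-validation step.
#'
#' @param balance A `balance_system`.
#' @return List with `lambda` and `residual` (sum of squared balance errors).
#' @export
fit_constant_rate <- function(balance) {
  u <- rowSums(balance$G)
  denom <- sum(u^2)
  lambda <- if (denom > 0) max(0, sum(u * balance$h) / denom) else 0
  list(lambda = lambda, residual = sum((lambda * u - balance$h)^2))
}

#' Cross-validated inference with a constant-rate test
#'
#' Guards against overfitting when the true rate barely depends on the
#' regulator: the snapshots are split into two equal halves; the free
#' regularized fit and the best constant rate are both obtained on the
#' training half and their balance-equation violations (sum of squared
#' errors of `G f = h` assembled from the validation half) are compared. If
#' the constant model's validation error is smaller or within a 5% margin of
#' the free fit's, a constant rate is refit on all data; otherwise the free
#' fit is refit on all data.
#'
#' @param samples A `snapshot_ensemble` with `N >= 2`.
#' @param degradation A [degradation_spec()].
#' @param epsilon Regularization strength for the free fits (defaults to the
#'   heuristic at the relevant sample size).
#' @param split_seed Seed for the random half split (determinism contract).
#' @param margin Relative margin of the decision rule (default 1.05).
#' @param constraint Passed to [infer_rate()].
#' @return A `rate_estimate` with `model` `"constant"` or `"free"` and a
#'   `cv` attribute recording both validation errors.
#' @export
infer_rate_cv <- function(samples, degradation, epsilon = NULL,
                          split_seed = 1, margin = 1.05,
                          constraint = "none") {
  N <- nrow(samples)
  if (N < 2) abort("cross-validation needs at least 2 samples.")
  set.seed(split_seed)
  idx <- sample.int(N)
  half <- idx[seq_len(N %/% 2)]
  train <- samples[half, ]
  valid <- samples[setdiff(idx, half), ]

  bal_train <- assemble_balance_system(empirical_joint(train), degradation)
  eps_train <- epsilon %||% default_epsilon(nrow(train))
  fit_free <- infer_rate(bal_train, epsilon = eps_train,
                         constraint = constraint)
  fit_const <- fit_constant_rate(bal_train)

  bal_valid <- assemble_balance_system(empirical_joint(valid), degradation)
  f_free_v <- rate_function(fit_free)(bal_valid$x2_states)
  err_free <- sum((bal_valid$G %*% f_free_v - bal_valid$h)^2)
  err_const <- sum((bal_valid$G %*% rep(fit_const$lambda,
                                        ncol(bal_valid$G)) - bal_valid$h)^2)

  bal_full <- assemble_balance_system(empirical_joint(samples), degradation)
  cv <- list(err_free = err_free, err_const = err_const, margin = margin,
             split_seed = split_seed)
  if (err_const <= margin * err_free) {
    fc <- fit_constant_rate(bal_full)
    out <- new_rate_estimate(
      x2 = bal_full$x2_states, f = rep(fc$lambda, ncol(bal_full$G)),
      px2 = bal_full$px2, epsilon = NA_real_, model = "constant",
      objective = fc$residual, degradation = degradation, n = N, cv = cv
    )
  } else {
    eps_full <- epsilon %||% default_epsilon(N)
    out <- infer_rate(bal_full, epsilon = eps_full, constraint = constraint)
    out$model <- "free"
    out$cv <- cv
  }
  out
}

#' Karush-Kuhn-Tucker optimality check
#'
#' Verifies that a returned estimate satisfies the first-order conditions of
#' the convex program solved by [infer_rate()]: the gradient of the
#' objective is (numerically) non-negative everywhere and zero on the active
#' set `f > 0`.
#'
#' @param balance The `balance_system` that produced the estimate.
#' @param estimate The `rate_estimate`.
#' @param tol Numerical tolerance.
#' @return List with `satisfied`, `min_gradient`, and
#'   `max_complementarity` (largest `|f_i * grad_i|`).
#' @export
check_kkt <- function(balance, estimate, tol = 1e-6) {
  G <- balance$G
  h <- balance$h
  n <- ncol(G)
  D2 <- second_difference_matrix(n)
  eps <- estimate$epsilon
  if (is.null(eps) || is.na(eps)) eps <- 0
  f <- estimate$estimate$f
  grad <- as.vector(2 * (t(G) %*% (G %*% f - h)) +
                      2 * eps * (t(D2) %*% (D2 %*% f)))
  scale <- max(1, max(abs(grad)))
  comp <- max(abs(f * grad)) / max(1, max(abs(f)))
  list(satisfied = min(grad) >= -tol * scale && comp <= tol * scale,
       min_gradient = min(grad), max_complementarity = comp)
}
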