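test_that("assemble_balance_system builds G and h as the cut equations", {
  # hand-built joint on x2 in {0,1}, x3 in {0,1,2}
  P <- matrix(c(0.1, 0.2,   # x3 = 0
                0.15, 0.25, # x3 = 1
                0.2, 0.1),  # x3 = 2
              nrow = 2)
  j <- joint_distribution(0:1, 0:2, P, n_source_samples = 100)
  bal <- assemble_balance_system(j, degradation_spec("linear", tau3 = 2))
  # cuts at m = 0, 1; G rows are P(x2 = ., x3 = m)
  expect_equal(dim(bal$G), c(2, 2))
  expect_equal(bal$G[1, ], c(0.1, 0.2))
  expect_equal(bal$G[2, ], c(0.15, 0.25))
  # h_m = (m + 1) P(x3 = m + 1) / tau3
  expect_equal(bal$h, c(1 * 0.4 / 2, 2 * 0.3 / 2))
  expect_equal(bal$x2_states, 0:1)
  expect_equal(bal$px2, rowSums(P))
  expect_equal(bal$n, 100L)
})

test_that("dimeric assembly uses the two-state downward flux and drops 2 rows", {
  P <- matrix(1 / 8, nrow = 2, ncol = 4) # x3 in 0..3
  j <- joint_distribution(0:1, 0:3, P)
  dg <- degradation_spec("dimeric", gamma = 3)
  bal <- assemble_balance_system(j, dg)
  expect_equal(length(bal$h), 2) # cuts at m = 0, 1 only
  p3 <- rep(1 / 4, 4)
  expect_equal(bal$h[1], 3 * 1 * 0 * p3[2] + 3 * 2 * 1 * p3[3])
  expect_equal(bal$h[2], 3 * 2 * 1 * p3[3] + 3 * 3 * 2 * p3[4])
})

test_that("exact balance: residuals vanish at the oracle distribution", {
  px <- poisson_fixture()
  bal <- assemble_balance_system(px$joint, degradation_spec("linear"))
  f_true <- rep(px$lambda, length(bal$x2_states))
  expect_lt(max(abs(bal$G %*% f_true - bal$h)), 1e-10)
})

test_that("inference recovers a constant rate from the exact joint", {
  # With constant production the joint factorizes, so the balance equations
  # pin down only the probability-weighted mean of f (any zero-curvature
  # rate with that mean is an exact optimum). The free fit must land on
  # that optimal face; the constant-rate model returns lambda itself.
  px <- poisson_fixture()
  bal <- assemble_balance_system(px$joint, degradation_spec("linear"))
  est <- infer_rate(bal, epsilon = 1e-10)
  w <- est$estimate$p_x2 / sum(est$estimate$p_x2)
  expect_lt(abs(sum(w * est$estimate$f) - px$lambda), 1e-5)
  expect_lt(max(abs(bal$G %*% est$estimate$f - bal$h)), 1e-8)
  kkt <- check_kkt(bal, est)
  expect_true(kkt$satisfied)
  const <- fit_constant_rate(bal)
  expect_lt(abs(const$lambda - px$lambda), 1e-8)
  expect_lt(const$residual, 1e-16)
})

test_that("default_epsilon follows the configured decreasing heuristic", {
  expect_equal(default_epsilon(1e4), 1e-2)
  expect_equal(default_epsilon(1e4, rule = "inverse_n"), 1e-4)
  expect_gt(default_epsilon(1e3), default_epsilon(1e5))
  expect_gt(default_epsilon(1e10), 0)
  expect_error(default_epsilon(0), "1")
  withr::with_options(list(ratesnap.epsilon_rule = "inverse_n"), {
    expect_equal(default_epsilon(100), 1 / 100)
  })
})

test_that("infer_rate validates inputs and honours epsilon", {
  px <- poisson_fixture()
  bal <- assemble_balance_system(px$joint, degradation_spec("linear"))
  expect_error(infer_rate(bal, epsilon = -1), "non-negative")
  e1 <- infer_rate(bal, epsilon = 0.5)
  expect_equal(e1$epsilon, 0.5)
  expect_s3_class(tidy(e1), "tbl_df")
  expect_named(tidy(e1), c("x2", "f", "p_x2", "reliable"))
  g <- glance(e1)
  expect_equal(g$model, "free")
  expect_equal(g$n_states, length(bal$x2_states))
})

test_that("estimates are non-negative and smoothness-regularized", {
  set.seed(4)
  # noisy joint around an increasing rate
  sys <- example_system("noise_enhancing")
  s <- motif_snapshots("noise_enhancing", 5000, seed = 4)
  bal <- assemble_balance_system(empirical_joint(s), sys$degradation)
  rough <- infer_rate(bal, epsilon = 0)
  smooth <- infer_rate(bal, epsilon = 10)
  expect_true(all(rough$estimate$f >= 0))
  expect_true(all(smooth$estimate$f >= 0))
  curv <- function(f) sum(diff(diff(f))^2)
  expect_lt(curv(smooth$estimate$f), curv(rough$estimate$f))
})

test_that("monotone constraints produce monotone estimates", {
  s <- motif_snapshots("noise_enhancing", 5000, seed = 4)
  sys <- example_system("noise_enhancing")
  bal <- assemble_balance_system(empirical_joint(s), sys$degradation)
  up <- infer_rate(bal, constraint = "increasing")
  down <- infer_rate(bal, constraint = "decreasing")
  expect_true(all(diff(up$estimate$f) >= -1e-9))
  expect_true(all(diff(down$estimate$f) <= 1e-9))
  # the true rate is increasing, so the increasing fit should do no worse
  free <- infer_rate(bal)
  E_up <- inference_error(up, sys$true_rate)$E
  expect_lt(E_up, 2 * inference_error(free, sys$true_rate)$E + 0.05)
})

test_that("rate_function looks up estimates with constant continuation", {
  est <- structure(list(estimate = tibble::tibble(
    x2 = c(2L, 4L, 6L), f = c(10, 20, 30),
    p_x2 = rep(1 / 3, 3), reliable = TRUE)), class = "rate_estimate")
  f <- rate_function(est)
  expect_equal(f(c(0, 2, 4, 6, 9)), c(10, 10, 20, 30, 30))
  expect_equal(f(5), 20)  # ties round down to the nearer-left state
  expect_equal(f(5.6), 30)
})

test_that("fit_constant_rate solves the one-parameter least squares", {
  px <- poisson_fixture()
  bal <- assemble_balance_system(px$joint, degradation_spec("linear"))
  fc <- fit_constant_rate(bal)
  expect_equal(fc$lambda, px$lambda, tolerance = 1e-8)
  expect_lt(fc$residual, 1e-15)
})

test_that("cross-validation split is reproducible and records errors", {
  s <- motif_snapshots("noise_enhancing", 5000, seed = 4)
  sys <- example_system("noise_enhancing")
  a <- infer_rate_cv(s, sys$degradation, split_seed = 2)
  b <- infer_rate_cv(s, sys$degradation, split_seed = 2)
  expect_equal(a$estimate$f, b$estimate$f)
  expect_true(all(c("err_free", "err_const") %in% names(a$cv)))
  expect_gt(a$cv$err_const, 0)
  expect_error(infer_rate_cv(s[0, ], sys$degradation), "at least 2")
})

test_that("scale unidentifiability: unknown tau3 rescales f but not its shape", {
  px <- poisson_fixture()
  bal1 <- assemble_balance_system(px$joint, degradation_spec("linear", tau3 = 1))
  bal2 <- assemble_balance_system(px$joint, degradation_spec("linear", tau3 = 2))
  f1 <- infer_rate(bal1, epsilon = 1e-10)$estimate$f
  f2 <- infer_rate(bal2, epsilon = 1e-10)$estimate$f
  expect_equal(f2, f1 / 2, tolerance = 1e-6)
})
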