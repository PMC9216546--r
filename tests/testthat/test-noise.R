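test_that("zero noise and full detection are exact identities", {
  s <- snapshot_ensemble(c(5, 6, 7), c(8, 9, 10))
  expect_identical(apply_additive(s, 0), s)
  expect_identical(apply_relative(s, 0), s)
  expect_identical(apply_undercount(s, 1), s)
  expect_identical(correct_undercount(s, 1), s)
})

test_that("corruption is seed-reproducible and integer-valued", {
  s <- motif_snapshots("noise_enhancing", 5000, seed = 4)
  a <- apply_additive(s, 3, seed = 9)
  b <- apply_additive(s, 3, seed = 9)
  expect_identical(a$x2, b$x2)
  expect_true(all(a$x2 == round(a$x2)) && all(a$x2 >= 0))
  r <- apply_relative(s, 0.1, seed = 9)
  expect_true(all(r$x3 >= 0))
  u <- apply_undercount(s, 0.5, seed = 9)
  expect_true(all(u$x2 <= s$x2) && all(u$x3 <= s$x3))
})

test_that("negative measurements are discarded and recorded", {
  s <- snapshot_ensemble(rep(1, 2000), rep(1, 2000))
  a <- apply_additive(s, 5, seed = 1)
  expect_lt(nrow(a), 2000)
  expect_equal(attr(a, "meta")$n_discarded, 2000 - nrow(a))
  expect_error(apply_additive(snapshot_ensemble(0, 0), 1e6, seed = 1),
               "discarded")
})

test_that("undercounting thins each coordinate binomially", {
  s <- snapshot_ensemble(rep(100, 5000), rep(60, 5000))
  u <- apply_undercount(s, 0.3, seed = 2)
  expect_equal(mean(u$x2), 30, tolerance = 0.02)
  expect_equal(mean(u$x3), 18, tolerance = 0.02)
  expect_equal(var(u$x2), 100 * 0.3 * 0.7, tolerance = 0.1)
  expect_error(apply_undercount(s, 0), "0, 1")
  expect_error(apply_undercount(s, 1.5), "0, 1")
})

test_that("correct_undercount rescales the x2 axis of data objects", {
  s <- snapshot_ensemble(c(10, 20), c(3, 4))
  cs <- correct_undercount(s, 0.5)
  expect_equal(cs$x2, c(20L, 40L))
  expect_equal(cs$x3, c(3L, 4L)) # x3 axis untouched for data objects
  j <- empirical_joint(snapshot_ensemble(c(1, 1, 2), c(0, 0, 0)))
  cj <- correct_undercount(j, 0.5)
  expect_equal(range(cj$x2), c(2, 4))
  expect_equal(marginal(cj, "x2")$p[match(c(2, 4), cj$x2)],
               c(2 / 3, 1 / 3))
})

test_that("correct_undercount on an estimate rescales axis and rate", {
  est <- structure(list(
    estimate = tibble::tibble(x2 = c(5L, 10L), f = c(2, 4),
                              p_x2 = c(0.5, 0.5), reliable = TRUE),
    scale_known = TRUE), class = "rate_estimate")
  ce <- correct_undercount(est, 0.5)
  expect_equal(ce$estimate$x2, c(10L, 20L))
  expect_equal(ce$estimate$f, c(4, 8)) # f divided by p
})

test_that("undercount of an estimate then evaluation matches the thinning law", {
  # the apparent rate on the measured axis is p * f(x2 / p); the correction
  # must restore f on the true axis
  f_true <- function(x) 3 + 0.5 * x
  x2_meas <- c(2L, 4L, 6L)
  est <- structure(list(
    estimate = tibble::tibble(x2 = x2_meas,
                              f = 0.5 * f_true(x2_meas / 0.5),
                              p_x2 = rep(1 / 3, 3), reliable = TRUE),
    scale_known = TRUE), class = "rate_estimate")
  ce <- correct_undercount(est, 0.5)
  expect_equal(ce$estimate$f, f_true(ce$estimate$x2))
})
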