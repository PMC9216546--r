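test_that("simulate_trajectory is seed-reproducible and tidy", {
  sys <- example_system("noise_enhancing")
  a <- simulate_trajectory(sys, t_end = 5, seed = 1)
  b <- simulate_trajectory(sys, t_end = 5, seed = 1)
  expect_identical(a, b)
  expect_true(all(c("time", "x1", "x2", "x3") %in% names(a)))
  expect_true(all(diff(a$time) >= 0))
  expect_true(all(as.matrix(a[, c("x1", "x2", "x3")]) >= 0))
  c <- simulate_trajectory(sys, t_end = 5, seed = 2)
  expect_false(identical(a, c))
})

test_that("sample_snapshots returns the requested ensemble deterministically", {
  sys <- example_system("noise_enhancing")
  s1 <- sample_snapshots(sys, 500, seed = 42)
  s2 <- sample_snapshots(sys, 500, seed = 42)
  expect_s3_class(s1, "snapshot_ensemble")
  expect_equal(nrow(s1), 500)
  expect_identical(s1$x2, s2$x2)
  expect_identical(s1$x3, s2$x3)
  expect_true(all(s1$x2 >= 0) && all(s1$x3 >= 0))
  meta <- attr(s1, "meta")
  expect_equal(meta$seed, 42)
  expect_gt(meta$burn_in, 0)
  expect_gt(meta$interval, 0)
})

test_that("default protocol scales burn-in and spacing with the slowest lifetime", {
  slow <- example_system("noise_controlling") # tau1 = 50
  fast <- example_system("noise_enhancing")   # all lifetimes 1
  m_slow <- attr(sample_snapshots(slow, 10, seed = 1), "meta")
  m_fast <- attr(sample_snapshots(fast, 10, seed = 1), "meta")
  expect_equal(m_slow$burn_in / m_fast$burn_in, 50)
  expect_equal(m_slow$interval / m_fast$interval, 50)
})

test_that("snapshots decorrelate under the default spacing", {
  sys <- example_system("noise_enhancing")
  s <- sample_snapshots(sys, 3000, seed = 7)
  ac <- snapshot_autocorrelation(s)
  expect_equal(ac$coordinate, c("x2", "x3"))
  expect_true(all(abs(ac$autocorrelation) < 0.2))
})

test_that("snapshot means agree with the exact stationary moments", {
  px <- poisson_fixture()
  s <- sample_snapshots(px$system, 4000, seed = 3)
  expect_equal(mean(s$x3), px$lambda, tolerance = 0.05)
  expect_equal(mean(s$x2), px$b2, tolerance = 0.05)
  expect_equal(var(s$x3) / mean(s$x3), 1, tolerance = 0.1) # Poisson Fano
})

test_that("snapshot ensembles round-trip through text files", {
  sys <- example_system("bistable")
  s <- sample_snapshots(sys, 200, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snapshots(s, path)
  back <- read_snapshots(path)
  expect_equal(back$x2, s$x2)
  expect_equal(back$x3, s$x3)
  expect_equal(attr(back, "meta")$seed, 5)
})

test_that("snapshot_ensemble constructor validates input", {
  expect_s3_class(snapshot_ensemble(c(1, 2), c(3, 4)), "snapshot_ensemble")
  expect_error(snapshot_ensemble(c(1, 2), c(3, 4, 5)))
  expect_error(snapshot_ensemble(c(-1, 2), c(3, 4)))
})
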