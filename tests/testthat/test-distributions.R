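test_that("empirical_joint counts and normalizes on the full rectangle", {
  e <- snapshot_ensemble(c(1, 1, 3, 3), c(2, 2, 4, 4))
  j <- empirical_joint(e)
  expect_equal(j$x2, 1:3)
  expect_equal(j$x3, 2:4)
  expect_equal(sum(j$prob), 1)
  expect_equal(j$prob[1, 1], 0.5)  # (x2=1, x3=2)
  expect_equal(j$prob[3, 3], 0.5)  # (x2=3, x3=4)
  expect_equal(j$prob[2, 2], 0)    # interior never observed, explicit zero
  expect_equal(j$n_source_samples, 4L)
})

test_that("joint_distribution validates support and mass", {
  expect_error(joint_distribution(c(0, 2), 0:1, matrix(1, 2, 2)),
               "contiguous")
  expect_error(joint_distribution(0:1, 0:1, matrix(-1, 2, 2)),
               "non-negative")
  expect_error(joint_distribution(0:1, 0:1, matrix(0, 2, 2)), "positive")
  # counts are normalized internally
  j <- joint_distribution(0:1, 0:1, matrix(c(2, 0, 0, 2), 2, 2))
  expect_equal(sum(j$prob), 1)
})

test_that("marginals and tidy() are consistent", {
  px <- poisson_fixture()
  j <- px$joint
  m2 <- marginal(j, "x2")
  m3 <- marginal(j, "x3")
  expect_equal(sum(m2$p), 1)
  expect_equal(names(m2), c("x2", "p"))
  d <- tidy(j)
  expect_equal(nrow(d), length(j$x2) * length(j$x3))
  expect_equal(sum(d$p), 1)
  agg <- d |> dplyr::group_by(x2) |> dplyr::summarise(p = sum(p))
  expect_equal(agg$p, m2$p)
})

test_that("conditional_mean matches hand computation and both input types", {
  e <- snapshot_ensemble(c(0, 0, 1, 1), c(2, 4, 6, 10))
  cm <- conditional_mean(e)
  expect_equal(cm$mean, c(3, 8))
  expect_equal(cm$p, c(0.5, 0.5))
  cm2 <- conditional_mean(empirical_joint(e))
  expect_equal(cm2$mean, cm$mean)
  expect_equal(cm2[[1]], c(0L, 1L))
})

test_that("sample_joint resamples the distribution it is given", {
  px <- poisson_fixture()
  s <- sample_joint(px$joint, 20000, seed = 1)
  expect_equal(nrow(s), 20000)
  expect_identical(s, sample_joint(px$joint, 20000, seed = 1))
  expect_lt(tv_distance(empirical_joint(s), px$joint), 0.06)
  expect_equal(mean(s$x3), px$lambda, tolerance = 0.05)
})

test_that("tv_distance is a metric-like comparison across supports", {
  px <- poisson_fixture()
  expect_equal(tv_distance(px$joint, px$joint), 0)
  shifted <- joint_distribution(px$joint$x2 + 5, px$joint$x3,
                                px$joint$prob)
  d <- tv_distance(px$joint, shifted)
  expect_gt(d, 0.5)
  expect_lte(d, 1)
})

test_that("joint distributions round-trip through text files", {
  e <- snapshot_ensemble(c(1, 1, 3, 3, 2), c(2, 2, 4, 4, 3))
  j <- empirical_joint(e)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_joint(j, p1, what = "prob")
  expect_equal(read_joint(p1)$prob, j$prob, tolerance = 1e-12)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_joint(j, p2, what = "count")
  back <- read_joint(p2)
  expect_equal(back$prob, j$prob)
  expect_equal(back$n_source_samples, 5L)
  # exact joints cannot be written as counts
  expect_error(write_joint(poisson_fixture()$joint, p1, what = "count"),
               "sample-backed")
})
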