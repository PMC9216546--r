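test_that("example_system builds the four motifs with the conserved part", {
  for (nm in c("noise_enhancing", "bistable", "oscillating",
               "noise_controlling")) {
    sys <- example_system(nm)
    expect_s3_class(sys, "reaction_system")
    expect_equal(sys$species, c("x1", "x2", "x3"))
    expect_length(sys$reactions, 6)
    expect_equal(sys$observed, c("x2", "x3"))
    # conserved downstream production: Hill(80, 2, 40) of x2
    expect_equal(sys$true_rate(40), 40)
    expect_equal(sys$true_rate(0), 0)
  }
  expect_error(example_system("unknown_motif"), "valid names")
})

test_that("noise_enhancing propensities match the printed rates", {
  sys <- example_system("noise_enhancing")
  X <- rbind(c(x1 = 3, x2 = 10, x3 = 50))
  A <- propensity_matrix(sys, X)
  expect_equal(A[1, 1], 5)                          # f1 constant
  expect_equal(A[1, 2], 3)                          # x1 / tau1
  expect_equal(A[1, 3], 25 * 50^4 / (50^4 + 50^4) + 8 * 3)
  expect_equal(A[1, 4], 10)                         # x2 / tau2
  expect_equal(A[1, 5], 80 * 10^2 / (40^2 + 10^2)) # f(x2)
  expect_equal(A[1, 6], 50)                         # x3 / tau3
})

test_that("dimeric variant removes two molecules at rate gamma x3 (x3 - 1)", {
  sys <- example_system("noise_enhancing", degradation = "dimeric")
  X <- rbind(c(x1 = 0, x2 = 0, x3 = 7))
  A <- propensity_matrix(sys, X)
  expect_equal(A[1, 6], 2 * 7 * 6)
  expect_equal(sys$reactions[[6]]$stoich[["x3"]], -2L)
  expect_equal(propensity_matrix(sys, rbind(c(0, 0, 1)))[1, 6], 0)
  expect_equal(propensity_matrix(sys, rbind(c(0, 0, 0)))[1, 6], 0)
  expect_s3_class(sys$degradation, "degradation_spec")
  expect_equal(sys$degradation$step, 2)
})

test_that("overrides touch declared parameters only and are validated", {
  sys <- example_system("noise_enhancing",
                        overrides = list(f3_lam = 20, f3_K = 10, tau2 = 2))
  expect_equal(sys$true_rate(10), 10)
  expect_equal(sys$lifetimes[["x2"]], 2)
  expect_error(example_system("noise_enhancing",
                              overrides = list(nonsense = 1)),
               "unknown override")
  # upstream overrides are motif-specific
  expect_error(example_system("noise_enhancing",
                              overrides = list(f1_n = 2)),
               "unknown override")
  sys2 <- example_system("oscillating", overrides = list(f2_K = 50))
  expect_equal(sys2$params$f2_K, 50)
})

test_that("x2_speed scales both x2 propensities and the declared lifetime", {
  base <- example_system("noise_enhancing")
  fast <- example_system("noise_enhancing", overrides = list(x2_speed = 40))
  X <- rbind(c(x1 = 2, x2 = 30, x3 = 60))
  expect_equal(propensity_matrix(fast, X)[1, 3],
               40 * propensity_matrix(base, X)[1, 3])
  expect_equal(propensity_matrix(fast, X)[1, 4],
               40 * propensity_matrix(base, X)[1, 4])
  # non-x2 reactions untouched
  expect_equal(propensity_matrix(fast, X)[1, c(1, 2, 5, 6)],
               propensity_matrix(base, X)[1, c(1, 2, 5, 6)])
  expect_equal(fast$lifetimes[["x2"]], 1 / 40)
})

test_that("example_system is deterministic", {
  a <- example_system("bistable")
  b <- example_system("bistable")
  X <- rbind(c(5, 20, 30), c(1, 2, 3))
  expect_identical(propensity_matrix(a, X), propensity_matrix(b, X))
})

test_that("built-in propensities are finite and non-negative on a grid", {
  grid <- as.matrix(expand.grid(x1 = c(0, 1, 50, 200),
                                x2 = c(0, 1, 50, 200),
                                x3 = c(0, 1, 50, 200)))
  for (nm in c("noise_enhancing", "bistable", "oscillating",
               "noise_controlling")) {
    A <- propensity_matrix(example_system(nm), grid)
    expect_true(all(is.finite(A)))
    expect_true(all(A >= 0))
  }
})

test_that("system configs round-trip through text serialization", {
  sys <- example_system("noise_controlling", degradation = "dimeric")
  path <- withr::local_tempfile(fileext = ".yml")
  write_system_config(sys, path)
  back <- read_system_config(path)
  X <- rbind(c(2, 4, 6), c(0, 0, 0), c(10, 80, 3))
  expect_equal(propensity_matrix(back, X), propensity_matrix(sys, X))
  expect_equal(back$species, sys$species)
  expect_equal(back$observed, sys$observed)
})

test_that("degradation_spec exposes the flux propensity g", {
  lin <- degradation_spec("linear", tau3 = 2)
  expect_equal(lin$g(10), 5)
  expect_equal(lin$step, 1)
  dim <- degradation_spec("dimeric", gamma = 2)
  expect_equal(dim$g(0:3), c(0, 0, 4, 12))
  expect_true(all(diff(dim$g(0:50)) >= 0))
})
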