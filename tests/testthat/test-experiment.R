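test_that("experiment configs round-trip through YAML", {
  cfg <- experiment_config("bistable", degradation = "dimeric",
                           overrides = list(f3_K = 20), n_samples = 1234,
                           noise = list(kind = "undercount", p_detect = 0.5,
                                        correct = TRUE),
                           cv = TRUE, seed = 99)
  path <- withr::local_tempfile(fileext = ".yml")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("run_experiment executes the full pipeline reproducibly", {
  cfg <- experiment_config("noise_enhancing", n_samples = 2000, seed = 5)
  res <- run_experiment(cfg)
  expect_s3_class(res, "ratesnap_result")
  expect_named(res$metrics, c("E", "I", "N", "model"))
  expect_equal(res$metrics$N, 2000L)
  expect_lt(res$metrics$E, 1)
  expect_gt(res$metrics$I, 0)
  expect_equal(res$metrics$model, "free")
  res2 <- run_experiment(cfg)
  expect_equal(res$metrics, res2$metrics)
  expect_equal(res$estimate$estimate$f, res2$estimate$estimate$f)
  expect_true(all(c("sim_seed", "noise_seed", "timings") %in%
                    names(res$provenance)))
})

test_that("run_experiment applies noise and the undercount correction", {
  cfg <- experiment_config("noise_enhancing", n_samples = 2000, seed = 5,
                           noise = list(kind = "undercount", p_detect = 0.5,
                                        correct = TRUE))
  res <- run_experiment(cfg)
  clean <- run_experiment(experiment_config("noise_enhancing",
                                            n_samples = 2000, seed = 5))
  # corrected axis reaches back out to the clean scale
  expect_gt(max(res$estimate$estimate$x2),
            0.8 * max(clean$estimate$estimate$x2))
  expect_error(
    run_experiment(experiment_config("noise_enhancing", n_samples = 100,
                                     seed = 1,
                                     noise = list(kind = "nope"))),
    "unknown noise kind")
})

test_that("sweep_experiment sweeps config fields and system overrides", {
  cfg <- experiment_config("noise_enhancing", n_samples = 1000, seed = 5)
  sw <- sweep_experiment(cfg, "n_samples", c(500, 1000))
  expect_equal(nrow(sw), 2)
  expect_equal(sw$value, c(500, 1000))
  expect_true(all(is.na(sw$error)))
  expect_true(all(sw$E > 0))
  sw2 <- sweep_experiment(cfg, "f3_K", c(20, 40))
  expect_equal(nrow(sw2), 2)
  expect_error(sweep_experiment(cfg, "not_a_param", 1:2), "config field")
})

test_that("a single-cell sweep reproduces run_experiment exactly", {
  cfg <- experiment_config("noise_enhancing", n_samples = 1000, seed = 7)
  direct <- run_experiment(cfg)
  sw <- sweep_experiment(cfg, "n_samples", 1000)
  expect_equal(sw$E, direct$metrics$E)
})

test_that("derived seeds are deterministic and distinct", {
  s <- vapply(1:50, function(i) ratesnap:::derive_seed(123, i), integer(1))
  expect_equal(s, vapply(1:50, function(i) ratesnap:::derive_seed(123, i),
                         integer(1)))
  expect_equal(length(unique(s)), 50)
  expect_true(all(s >= 0 & s < 2^31))
})
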