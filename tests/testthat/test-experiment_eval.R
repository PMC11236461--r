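test_that("bias, accuracy and precision follow the scoring definitions", {
  expect_equal(bias(c(8, 9), 10, scale_by_truth = TRUE), -0.15)
  expect_equal(bias(c(10, 10), 10), 0)
  expect_equal(bias(c(9, 11), 10), 0)
  expect_true(is.na(bias(c(1, 2), 0, scale_by_truth = TRUE)))

  expect_equal(accuracy(c(9, 11), 10), -1)
  expect_equal(accuracy(c(10, 10), 10), 0)
  expect_equal(accuracy(c(8, 9), 10, scale_by_truth = TRUE), -0.15)

  expect_equal(precision(c(5, 5, 5)), 0)
  expect_equal(precision(c(9, 11)), -sqrt(2) / 10)
  expect_true(is.na(precision(c(-1, 1))))

  # accuracy <= -|bias| (triangle inequality), precision <= 0
  set.seed(26)
  for (i in 1:20) {
    est <- rnorm(sample(2:10, 1), 5, 2)
    expect_lte(accuracy(est, 4.2), -abs(bias(est, 4.2)) + 1e-12)
    expect_lte(precision(est), 0)
  }
})

test_that("the factorial design enumerates to the published totals", {
  full <- experiment_config()
  d <- enumerate_design(full)
  expect_equal(d$n_combinations, 81)
  expect_equal(d$n_communities, 2835)
  expect_equal(d$n_datasets, 28350)
  expect_equal(full$communities_per_combo, 35)
  expect_equal(full$sampling_reps_per_community, 10)

  # scenario labels follow the Table-1 grid order
  scen <- detection_scenarios()
  expect_equal(scen$scenario_id, paste0("S", 1:9))
  expect_equal(scen$mu[scen$scenario_id == "S5"], 0.05)
  expect_equal(scen$sigma[scen$scenario_id == "S5"], 1.0)
  expect_equal(scen$mu, rep(c(0.005, 0.05, 0.2), each = 3))
  expect_equal(scen$sigma, rep(c(0.25, 1, 3), 3))
  expect_true(all(d$grid$scenario_id %in% scen$scenario_id))
})

test_that("a desk-profile run is complete and bit-reproducible", {
  cfg <- experiment_config_desk(n_patches = 10, n_species = 40,
                                communities_per_combo = 2,
                                sampling_reps_per_community = 3,
                                master_seed = 99)
  res <- run_experiment(cfg)
  perf <- res$performance
  expect_s3_class(perf, "data.frame")
  # complete record: 6 parameters x 2 methods
  expect_equal(nrow(perf), 12)
  expect_setequal(unique(perf$parameter),
                  c("richness", "sorensen", "c_value", "z_value",
                    "gamma0", "gamma1"))
  expect_setequal(unique(perf$method), c("observed", "chao"))
  expect_true(all(perf$n_replicates == 6))
  expect_true(all(is.finite(perf$bias)))
  expect_true(all(perf$accuracy <= 0))
  expect_true(all(perf$precision <= 0))

  res2 <- run_experiment(cfg)
  expect_identical(res$performance, res2$performance)
  expect_identical(res$raw, res2$raw)
})

test_that("perfect detection zeroes observed-count bias and accuracy", {
  cfg <- experiment_config_desk(n_patches = 10, n_species = 40,
                                communities_per_combo = 1,
                                sampling_reps_per_community = 2,
                                methods = "observed", master_seed = 5)
  res <- run_experiment(cfg, perfect = TRUE)
  perf <- res$performance
  expect_equal(nrow(perf), 6)
  expect_equal(perf$bias, rep(0, 6), tolerance = 1e-10)
  expect_equal(perf$accuracy, rep(0, 6), tolerance = 1e-10)
})

test_that("landscape and survey tables round-trip through text", {
  land <- tiny_landscape(seed = 31)
  dir <- withr::local_tempdir()
  write_landscape(land, file.path(dir, "land"))
  land2 <- read_landscape(file.path(dir, "land"))
  expect_equal(land2$patch_areas, land$patch_areas)
  expect_equal(unname(land2$N), unname(land$N))
  expect_equal(land2$metacommunity$abundances,
               land$metacommunity$abundances)

  svy <- sample_landscape(land, mu = 0.2, sigma = 1, V = 3, seed = 32)
  write_survey(svy, file.path(dir, "svy"))
  svy2 <- read_survey(file.path(dir, "svy"))
  expect_identical(svy2$X, svy$X)
  expect_identical(svy2$pooled, svy$pooled)
  expect_identical(svy2$Y, svy$Y)
})

test_that("the CLI toy and simulate subcommands emit the artifact set", {
  dir <- withr::local_tempdir()
  suppressMessages(fragsar_cli(c("toy", "--out", file.path(dir, "toy"))))
  expect_true(file.exists(file.path(dir, "toy", "landscape", "abundance.tsv")))
  expect_true(file.exists(file.path(dir, "toy", "survey", "counts_long.tsv")))
  land <- read_landscape(file.path(dir, "toy", "landscape"))
  expect_equal(length(land$patch_areas), 6)

  suppressMessages(fragsar_cli(c("simulate", "--n-patches", "8",
                                 "--n-species", "25", "--seed", "3",
                                 "--out", file.path(dir, "sim"))))
  land2 <- read_landscape(file.path(dir, "sim"))
  expect_equal(land2$metacommunity$n_species, 25)
})
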