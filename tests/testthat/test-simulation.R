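test_that("random covariances hit the target volume exactly and vary in shape", {
  set.seed(51)
  for (target in c(5, 7.5, 20)) {
    for (i in 1:20) {
      s <- random_covariance_for_sev(target)
      expect_equal(sev_from_covariance(s), target, tolerance = 1e-9)
    }
  }
  # d = 2 target is an area
  expect_equal(sev_from_covariance(random_covariance_for_sev(5, d = 2)), 5,
               tolerance = 1e-9)
  # shape diversity: correlations span both signs with non-degenerate spread
  cors <- replicate(2000, {
    s <- random_covariance_for_sev(5)
    s[1, 2] / sqrt(s[1, 1] * s[2, 2])
  })
  expect_lt(min(cors), -0.3)
  expect_gt(max(cors), 0.3)
  expect_gt(sd(cors), 0.1)
})

test_that("rescaling a generated covariance follows the volume scaling law", {
  s <- random_covariance_for_sev(5, seed = 52)
  expect_equal(sev_from_covariance(s * 2^(2 / 3)), 10, tolerance = 1e-9)
})

test_that("simulated datasets have the right shape and are seed-deterministic", {
  spec <- population_spec(c(0, 0, 0), 5)
  d6 <- simulate_isotope_data(spec, 6, seed = 53)
  expect_equal(nrow(d6), 6)
  expect_equal(names(d6), c("id", "group", "d13C", "d15N", "d34S"))
  expect_identical(
    as.matrix(simulate_isotope_data(spec, 6, seed = 53)[, 3:5]),
    as.matrix(d6[, 3:5]))
  expect_equal(dim(attr(d6, "sigma_true")), c(3, 3))
  d2 <- simulate_isotope_data(population_spec(c(0, 0), 5), 6, seed = 54)
  expect_equal(names(d2), c("id", "group", "d13C", "d15N"))
})

test_that("large simulated samples recover the generating moments", {
  d <- simulate_isotope_data(population_spec(c(0, 0, 0), 5), 1e5, seed = 55)
  y <- as.matrix(d[, 3:5])
  expect_lt(max(abs(colMeans(y))), 0.05)
  expect_equal(sev_from_covariance(cov(y)), 5, tolerance = 0.02)
  expect_equal(unname(cov(y)), attr(d, "sigma_true"), tolerance = 0.05)
})

test_that("a minimal study runs, is deterministic, and is resumable", {
  cfg <- study_config(
    populations = list(population_spec(c(0, 0, 0), 5, "a"),
                       population_spec(c(2, 2, 2), 10, "b")),
    sample_sizes = 10, n_datasets = 2,
    mcmc = mcmc_control(600, 150), master_seed = 7)
  res <- run_simulation_study(cfg)
  expect_equal(nrow(res), 4)
  expect_true(all(!is.na(res$sev_median)))
  expect_true(all(is.na(res$p_sev_greater_ref[res$population == "a"])))
  expect_true(all(!is.na(res$p_sev_greater_ref[res$population == "b"])))
  expect_true(all(res$ci_covers_truth %in% c(TRUE, FALSE)))
  expect_equal(res$ci_covers_truth,
               res$sev_ci_lo <= res$true_sev & res$true_sev <= res$sev_ci_hi)
  # determinism under the master seed
  res2 <- run_simulation_study(cfg)
  expect_equal(as.data.frame(res), as.data.frame(res2))
  # resumable: previously computed cells are reused as-is
  res3 <- run_simulation_study(cfg, previous = res[1:3, ])
  expect_equal(as.data.frame(res3), as.data.frame(res))
})

test_that("per-cell seeds derived from the master seed are distinct", {
  seeds <- c(seed_mix(1, 1, 6, 1), seed_mix(1, 1, 6, 2),
             seed_mix(1, 2, 6, 1), seed_mix(1, 1, 10, 1),
             seed_mix(2, 1, 6, 1))
  expect_equal(length(unique(seeds)), 5)
  expect_true(all(seeds >= 1 & seeds < 2^31))
})

test_that("power is ordered by effect size and null pairs sit near one half", {
  cfg <- study_config(
    populations = standard_populations(),
    sample_sizes = 6, n_datasets = 30,
    mcmc = mcmc_control(1500, 400), master_seed = 11)
  res <- cached_study("order6", cfg)
  pc <- power_curves(res)
  p2 <- pc$power_median[pc$population == "pop2"]
  p3 <- pc$power_median[pc$population == "pop3"]
  p4 <- pc$power_median[pc$population == "pop4"]
  expect_true(p4 >= p3 && p3 >= p2)
  expect_error(power_curves(res, pair = "nonexistent"), "nonexistent")

  null_cfg <- study_config(
    populations = list(population_spec(c(0, 0, 0), 5, "ref"),
                       population_spec(c(0, 0, 0), 5, "same")),
    sample_sizes = 20, n_datasets = 60,
    mcmc = mcmc_control(1500, 400), master_seed = 12)
  null_res <- run_simulation_study(null_cfg)
  pnull <- power_curves(null_res)
  expect_lt(abs(pnull$power_median - 0.5), 0.2)
})

test_that("centroid-distance estimates are nearly unbiased at moderate n", {
  cfg <- study_config(
    populations = list(population_spec(c(0, 0, 0), 5, "pop1"),
                       population_spec(c(1, 1, 1), 7.5, "pop2")),
    sample_sizes = 50, n_datasets = 50,
    mcmc = mcmc_control(1500, 400), master_seed = 13)
  res <- run_simulation_study(cfg)
  est <- res$distance_ref_median[res$population == "pop2"]
  expect_equal(mean(est), sqrt(3), tolerance = 0.1)
})
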