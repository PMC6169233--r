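test_that("sampled factors stay on their uniform supports", {
  cfg <- simulation_config("adult_trespasser", "oral", n_iterations = 500,
                           seed = 11)
  s <- sample_scenario(cfg, table1_scenario("adult_trespasser", "oral"),
                       n = 500)
  expect_true(all(s$params$BW >= 60 & s$params$BW <= 100))
  expect_true(all(s$params$EF >= 30 & s$params$EF <= 50))
  expect_true(all(s$params$IR_S >= 15 & s$params$IR_S <= 25))
  # fixed factors pass through unchanged
  expect_equal(s$params$CS, 0.283)
  expect_equal(s$params$AT, 25550)
})

test_that("identical seeds reproduce draws bit for bit", {
  cfg <- simulation_config("child_trespasser", "dermal",
                           n_iterations = 200, seed = 99)
  expect_identical(simulate_risk(cfg), simulate_risk(cfg))
  cfg2 <- simulation_config("child_trespasser", "dermal",
                            n_iterations = 200, seed = 100)
  expect_false(identical(as.numeric(simulate_risk(cfg)),
                         as.numeric(simulate_risk(cfg2))))
})

test_that("an all-fixed configuration collapses to the point estimate", {
  dist <- table1_distributions("adult_trespasser", "oral")
  dist$kind <- "fixed"
  dist$half_width <- 0
  cfg <- simulation_config("adult_trespasser", "oral", n_iterations = 50,
                           seed = 5, distributions = dist)
  risks <- simulate_risk(cfg)
  point <- compute_risk(table1_scenario("adult_trespasser", "oral"),
                        cancer_slopes("oral"))
  expect_length(risks, 50)
  expect_true(all(as.numeric(risks) == point))
})

test_that("the simulated mean agrees with the closed-form expectation", {
  # independent factors: E[risk] = CS*CF/AT * E[IR]E[EF]E[ED]E[1/BW] * sumCSF
  # with E[1/BW] = log(b/a)/(b-a) for BW ~ U(a, b)
  cfg <- simulation_config("adult_trespasser", "oral",
                           n_iterations = 10000, seed = 21)
  risks <- as.numeric(simulate_risk(cfg))
  expected <- 0.283 * 1e-6 / 25550 * 20 * 40 * 20 *
    (log(100 / 60) / 40) * 16.8703
  se <- sd(risks) / sqrt(length(risks))
  expect_lt(abs(mean(risks) - expected), 3 * se)
  expect_true(all(risks > 0))
})

test_that("raising the sediment concentration scales every draw", {
  base <- table1_scenario("adult_trespasser", "oral")
  cfg <- simulation_config("adult_trespasser", "oral", n_iterations = 100,
                           seed = 8)
  r1 <- as.numeric(simulate_risk(cfg, base = base))
  p2 <- base$params
  p2$CS <- p2$CS * 2.5
  r2 <- as.numeric(simulate_risk(cfg, base = exposure_scenario(
    base$group, base$route, p2)))
  expect_equal(r2, 2.5 * r1, tolerance = 1e-12)
})

test_that("child groups dominate adults in mean simulated risk", {
  for (route in exposure_routes()) {
    means <- vapply(exposure_groups(), function(g) {
      mean(simulate_risk(simulation_config(g, route, n_iterations = 2000,
                                           seed = 17)))
    }, numeric(1))
    expect_gt(means[["child_trespasser"]], means[["adult_trespasser"]])
    expect_gt(means[["child_recreational"]], means[["adult_recreational"]])
  }
})

test_that("distribution summaries satisfy their order invariants", {
  risks <- as.numeric(simulate_risk(
    simulation_config("adult_recreational", "dermal",
                      n_iterations = 3000, seed = 31)))
  summ <- summarize_distribution(risks)
  expect_lte(summ$minimum, summ$median)
  expect_lte(summ$median, summ$maximum)
  expect_lte(summ$percentile_2.5, summ$median)
  expect_lte(summ$median, summ$percentile_97.5)
  expect_lte(summ$ci95_lower, summ$mean)
  expect_gte(summ$ci95_upper, summ$mean)
  expect_equal(summ$n, 3000)
  # permutation invariance
  expect_equal(summarize_distribution(rev(risks)), summ)
})

test_that("degenerate and empty collections are handled", {
  const <- rep(4.2e-8, 1000)
  summ <- summarize_distribution(const)
  expect_equal(summ$sd, 0)
  expect_equal(summ$ci95_upper - summ$ci95_lower, 0)
  expect_equal(summ$percentile_2.5, 4.2e-8)
  expect_equal(summ$percentile_97.5, 4.2e-8)
  expect_error(summarize_distribution(numeric(0)),
               class = "pahrisk_validation_error")
})

test_that("bootstrap CI of the mean brackets the normal-approximation CI", {
  set.seed(1)
  risks <- as.numeric(simulate_risk(
    simulation_config("adult_trespasser", "oral", n_iterations = 2000,
                      seed = 3)))
  norm_ci <- summarize_distribution(risks)
  boot_ci <- summarize_distribution(risks, ci_method = "bootstrap")
  expect_equal(boot_ci$ci95_lower, norm_ci$ci95_lower, tolerance = 0.05)
  expect_equal(boot_ci$ci95_upper, norm_ci$ci95_upper, tolerance = 0.05)
})

test_that("histograms conserve counts and cover the range", {
  risks <- as.numeric(simulate_risk(
    simulation_config("child_recreational", "oral", n_iterations = 10000,
                      seed = 13)))
  h <- export_histogram(risks, bins = 20)
  expect_equal(nrow(h), 20)
  expect_equal(sum(h$count), 10000)
  expect_equal(h$bin_lower[1], min(risks))
  expect_equal(h$bin_upper[nrow(h)], max(risks))
  # constant input occupies a single bin
  h1 <- export_histogram(rep(1e-8, 50), bins = 7)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$count, 50)
  expect_error(export_histogram(risks, bins = 0),
               class = "pahrisk_validation_error")
  # seeded rerun reproduces the histogram
  risks2 <- as.numeric(simulate_risk(
    simulation_config("child_recreational", "oral", n_iterations = 10000,
                      seed = 13)))
  expect_identical(export_histogram(risks2, bins = 20), h)
})

test_that("malformed configurations are rejected with config errors", {
  dist <- table1_distributions("adult_trespasser", "oral")
  bad <- dist
  bad$symbol[1] <- "XX"
  expect_error(simulation_config("adult_trespasser", "oral",
                                 distributions = bad),
               class = "pahrisk_config_error")
  expect_error(simulation_config("adult_trespasser", "oral",
                                 distributions = dist[dist$symbol != "BW", ]),
               class = "pahrisk_config_error")
  wide <- dist
  wide$half_width[wide$symbol == "BW"] <- 80
  expect_error(simulation_config("adult_trespasser", "oral",
                                 distributions = wide),
               class = "pahrisk_config_error")
  expect_error(simulation_config("adult_trespasser", "oral",
                                 distributions = rbind(dist, dist[1, ])),
               class = "pahrisk_config_error")
})

test_that("the truncated-normal family stays on the same support", {
  cfg <- simulation_config("adult_trespasser", "oral", n_iterations = 400,
                           seed = 2, family = "truncnorm")
  s <- sample_scenario(cfg, table1_scenario("adult_trespasser", "oral"),
                       n = 400)
  expect_true(all(s$params$BW >= 60 & s$params$BW <= 100))
  # mass concentrates near the center relative to uniform
  expect_lt(sd(s$params$BW), 20 / sqrt(3))
})
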