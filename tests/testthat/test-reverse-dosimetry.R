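unit_kinetics <- function() {
  data.frame(parent = "p", metabolite = "m", mw_parent = 1,
             mw_metabolite = 1, excretion_fraction = 0.5)
}

test_that("single-record intake matches the hand-evaluated quotient", {
  # 10 ug/L * 1.5 L/day * 1 / (0.5 * 75 kg * 1) = 15 / 37.5 = 0.4
  got <- estimate_intake(list(metabolite = "m", concentration = 10),
                         unit_kinetics(), population_constants(1.5, 75))
  expect_equal(got, 0.4, tolerance = 1e-12)
  expect_equal(estimate_intake(list(metabolite = "m", concentration = 0),
                               unit_kinetics(), population_constants(1.5, 75)),
               0)
})

test_that("intake is linear and inverse-linear in the right factors", {
  k <- unit_kinetics()
  cst <- population_constants(1.5, 75)
  base <- estimate_intake(list(metabolite = "m", concentration = 10), k, cst)
  expect_equal(estimate_intake(list(metabolite = "m", concentration = 20),
                               k, cst), 2 * base)
  k2 <- k; k2$excretion_fraction <- 1
  expect_equal(estimate_intake(list(metabolite = "m", concentration = 10),
                               k2, cst), base / 2)
  k3 <- k; k3$mw_metabolite <- 2
  expect_equal(estimate_intake(list(metabolite = "m", concentration = 10),
                               k3, cst), base / 2)
  cst2 <- population_constants(3, 75)
  expect_equal(estimate_intake(list(metabolite = "m", concentration = 10),
                               k, cst2), 2 * base)
})

test_that("mismatched metabolites and degenerate kinetics are rejected", {
  expect_error(estimate_intake(list(metabolite = "other", concentration = 1),
                               unit_kinetics(), population_constants()),
               class = "pahrisk_validation_error")
  bad <- unit_kinetics()
  bad$excretion_fraction <- 0
  expect_error(estimate_intake(list(metabolite = "m", concentration = 1),
                               bad, population_constants()),
               class = "pahrisk_validation_error")
})

test_that("population estimation yields one intake per parent and stratum", {
  spec <- synthesis_spec(seed = 4)
  bio <- generate_biomarkers(spec)   # 4 parents x 3 smoking strata
  est <- estimate_population(bio)
  expect_equal(nrow(est), 12)
  expect_setequal(unique(est$parent),
                  c("naphthalene", "fluorene", "phenanthrene", "pyrene"))
  # identical concentrations in two strata give identical intakes
  flat <- bio
  flat$concentration <- 5
  est_flat <- estimate_population(flat)
  expect_equal(length(unique(tapply(est_flat$intake, est_flat$parent,
                                    function(x) diff(range(x))))), 1)
  expect_true(all(tapply(est_flat$intake, est_flat$parent,
                         function(x) diff(range(x))) == 0))
})

test_that("a metabolite without kinetics is reported by name", {
  bio <- tibble::tibble(metabolite = "9-hydroxymystery", concentration = 1,
                        gender = "all", race_ethnicity = "all",
                        smoking_status = "all")
  expect_error(estimate_population(bio), regexp = "9-hydroxymystery",
               class = "pahrisk_validation_error")
})

test_that("round trip recovers known intakes exactly at zero noise", {
  spec <- synthesis_spec(seed = 6, noise_cv = 0)
  bio <- generate_biomarkers(spec, axes = c("smoking_status", "gender"))
  truth <- attr(bio, "true_intakes")
  est <- estimate_population(bio)
  m <- merge(est, truth,
             by = c("parent", "gender", "race_ethnicity", "smoking_status"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$intake, m$true_intake, tolerance = 1e-12)
})

test_that("smoking strata rank by construction and ties fall back to names", {
  spec <- synthesis_spec(seed = 7)
  est <- estimate_population(generate_biomarkers(spec))
  ranking <- rank_strata(est, "smoking_status")
  expect_equal(ranking$level, c("smoker", "secondhand", "nonsmoker"))
  # all-equal intakes rank alphabetically
  tied <- est
  tied$intake <- 1
  expect_equal(rank_strata(tied, "smoking_status")$level,
               sort(unique(est$smoking_status)))
  # invariant to row order and to positive rescaling
  shuffled <- est[sample.int(nrow(est)), ]
  expect_equal(rank_strata(shuffled, "smoking_status"), ranking)
  scaled <- est
  scaled$intake <- est$intake * 17.3
  expect_equal(rank_strata(scaled, "smoking_status")$level, ranking$level)
  expect_error(rank_strata(est, "shoe_size"),
               class = "pahrisk_validation_error")
})
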