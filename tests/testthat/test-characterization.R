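test_that("pooling sums records over the compound set", {
  tab <- toy_characterization()
  pooled <- pool_mixture(tab, c("X", "Y"))
  expect_true(all(pooled$compound == "mixture"))
  cell <- pooled[pooled$compartment == "fresh_water" &
                   pooled$route == "fish", ]
  expect_equal(cell$intake_fraction, 0.1 + 0.2)
  # single-compound pooling is the identity on quantities
  solo <- pool_mixture(tab, "X")
  orig <- tab[tab$compound == "X", ]
  m <- merge(solo, orig, by = c("compartment", "route"))
  expect_equal(m$intake_fraction.x, m$intake_fraction.y)
  expect_error(pool_mixture(tab, c("X", "Z", "W")), regexp = "Z, W",
               class = "pahrisk_validation_error")
})

test_that("pooled totals equal a brute-force per-cell loop", {
  spec <- synthesis_spec(seed = 12)
  tab <- generate_characterization(spec)
  comps <- coc_names()
  pooled <- pool_mixture(tab, comps)
  for (i in sample.int(nrow(pooled), 5)) {
    rows <- tab[tab$compartment == pooled$compartment[i] &
                  tab$route == pooled$route[i] &
                  tab$compound %in% comps, ]
    expect_equal(pooled$intake_fraction[i], sum(rows$intake_fraction))
    expect_equal(pooled$cancer_cases_per_kg[i],
                 sum(rows$cancer_cases_per_kg))
  }
})

test_that("route shares normalize to one and identify the dominant route", {
  spec <- synthesis_spec(seed = 14)
  tab <- generate_characterization(spec)
  pooled <- pool_mixture(tab, coc_names())
  for (cp in unique(pooled$compartment)) {
    shares <- route_apportionment(pooled, cp)
    expect_equal(sum(shares$share), 1, tolerance = 1e-12)
    expect_equal(shares$route[1], "fish")
  }
  # single-route compartment takes the whole share
  one <- characterization_table(data.frame(
    compound = "X", compartment = "pond", route = "fish",
    intake_fraction = 0.4, cancer_cases_per_kg = 0, daly_per_kg = 0
  ))
  expect_equal(route_apportionment(one, "pond")$share, 1)
  zero <- characterization_table(data.frame(
    compound = "X", compartment = "pond", route = "fish",
    intake_fraction = 0, cancer_cases_per_kg = 0, daly_per_kg = 0
  ))
  expect_error(route_apportionment(zero, "pond"),
               class = "pahrisk_validation_error")
})

test_that("compartment effects reproduce the construction ordering", {
  ordering <- c("fresh_water", "sea_water", "agricultural_soil",
                "natural_soil")
  tab <- generate_characterization(synthesis_spec(seed = 15,
                                                  cf_ordering = ordering))
  eff <- effects_by_compartment(tab, coc_names())
  expect_equal(eff$compartment, ordering)
  expect_true(all(diff(eff$cancer_cases_per_kg) < 0))
  expect_true(all(diff(eff$daly_per_kg) < 0))
  # all-zero effects pass through as zeros
  z <- toy_characterization()
  z$cancer_cases_per_kg <- 0
  z$daly_per_kg <- 0
  expect_true(all(effects_by_compartment(z, c("X", "Y"))$daly_per_kg == 0))
})

test_that("pooled effects equal the sum of single-compound calls", {
  tab <- toy_characterization()
  both <- effects_by_compartment(tab, c("X", "Y"))
  x <- effects_by_compartment(tab, "X")
  y <- effects_by_compartment(tab, "Y")
  m <- merge(merge(both, x, by = "compartment"), y, by = "compartment")
  expect_equal(m$cancer_cases_per_kg.x,
               m$cancer_cases_per_kg.y + m$cancer_cases_per_kg)
  expect_equal(m$intake_fraction.x,
               m$intake_fraction.y + m$intake_fraction)
})

test_that("adding a compound never decreases pooled totals", {
  tab <- toy_characterization()
  one <- pool_mixture(tab, "X")
  two <- pool_mixture(tab, c("X", "Y"))
  m <- merge(one, two, by = c("compartment", "route"))
  expect_true(all(m$intake_fraction.y >= m$intake_fraction.x))
  expect_true(all(m$daly_per_kg.y >= m$daly_per_kg.x))
})

test_that("schema violations are caught", {
  bad <- toy_characterization()
  bad$intake_fraction[1] <- -0.1
  expect_error(characterization_table(bad),
               class = "pahrisk_validation_error")
  dup <- rbind(toy_characterization(), toy_characterization()[1, ])
  expect_error(characterization_table(dup),
               class = "pahrisk_validation_error")
  expect_error(characterization_table(data.frame(compound = "X")),
               class = "pahrisk_schema_error")
})
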