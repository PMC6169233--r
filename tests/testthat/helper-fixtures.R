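# Shared helpers: tiny in-code fixtures for the unit tests.

coc_names <- function() names(cancer_slopes("oral"))

toy_mixture_df <- function() {
  data.frame(
    name = c("A", "B", "C"),
    concentration = c(3, 2, 1),
    concentration_sd = c(0.3, 0.2, 0.1),
    is_priority = c(TRUE, FALSE, TRUE),
    concern_level = c("high", "none", "low")
  )
}

toy_characterization <- function() {
  grid <- expand.grid(
    compound = c("X", "Y"),
    compartment = c("fresh_water", "sea_water"),
    route = c("fish", "drinking_water"),
    stringsAsFactors = FALSE
  )
  grid$intake_fraction <- c(0.1, 0.2, 0.05, 0.1, 0.02, 0.04, 0.01, 0.02)
  grid$cancer_cases_per_kg <- grid$intake_fraction * 1e-3
  grid$daly_per_kg <- grid$intake_fraction * 1e-2
  characterization_table(grid)
}
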