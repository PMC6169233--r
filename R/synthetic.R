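# Synthetic-data generators: every input the pipeline consumes can be
# produced with known ground truth, so each stage is testable end to end
# without external downloads. All generators are deterministic under the
# spec's seed.

#' Specification for synthetic input generation
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_compounds Number of compounds for synthetic mixtures.
#' @param concentration_scale Upper concentration scale, ng/mL; synthetic
#'   mixture concentrations are log-uniform on
#'   `[concentration_scale/1000, concentration_scale]`.
#' @param true_intakes Named vector of ground-truth baseline daily intakes
#'   (ug/kg-day) per parent PAH. The defaults put naphthalene highest,
#'   matching its dominance among biomonitored PAHs.
#' @param stratum_effects Named multiplicative factors applied to the
#'   baseline intake per stratum level (levels not named get factor 1).
#'   Defaults encode heavier exposure for smokers (3x), secondhand-exposed
#'   (1.5x) and non-Hispanic black participants (1.5x).
#' @param cf_ordering Compartment ordering for synthetic characterization
#'   tables; effect factors decrease strictly along it.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise on synthetic biomarker concentrations (0 = noiseless).
#' @return A `synthesis_spec` list.
#' @export
synthesis_spec <- function(seed = 1,
                           n_compounds = 35,
                           concentration_scale = 1600,
                           true_intakes = c(naphthalene = 0.30,
                                            fluorene = 0.05,
                                            phenanthrene = 0.08,
                                            pyrene = 0.04),
                           stratum_effects = c(smoker = 3,
                                               secondhand = 1.5,
                                               nonsmoker = 1,
                                               `non-Hispanic black` = 1.5),
                           cf_ordering = c("fresh_water", "sea_water",
                                           "agricultural_soil",
                                           "natural_soil"),
                           noise_cv = 0) {
  if (concentration_scale <= 0 || any(true_intakes <= 0)) {
    abort("scales and true intakes must be positive",
          class = "pahrisk_validation_error")
  }
  if (noise_cv < 0) {
    abort("noise_cv must be nonnegative", class = "pahrisk_validation_error")
  }
  if (any(stratum_effects <= 0)) {
    abort("stratum effects must be positive multiplicative factors",
          class = "pahrisk_validation_error")
  }
  structure(list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
                 concentration_scale = concentration_scale,
                 true_intakes = true_intakes,
                 stratum_effects = stratum_effects,
                 cf_ordering = cf_ordering, noise_cv = noise_cv),
            class = "synthesis_spec")
}

#' Generate a synthetic mixture profile
#'
#' Draws log-uniform concentrations, assigns priority flags and concern
#' levels from a frequency table mirroring the packaged sediment mixture.
#' With `preset = "paper"`, returns the packaged measured profile itself.
#'
#' @param spec A [synthesis_spec()].
#' @param preset `NULL` for synthetic output, or `"paper"` for the packaged
#'   sediment mixture fixture.
#' @param priority_prob Probability a synthetic compound is flagged as an
#'   EPA priority PAH.
#' @param concern_probs Named probabilities over [concern_levels()] for
#'   synthetic concern assignments; default mirrors the packaged mixture.
#' @return A [mixture_profile()].
#' @export
generate_mixture <- function(spec, preset = NULL,
                             priority_prob = 16 / 35,
                             concern_probs = c(none = 20, marginal = 0,
                                               low = 4, `low-moderate` = 4,
                                               moderate = 3,
                                               `moderate-high` = 1,
                                               high = 3) / 35) {
  if (!is.null(preset)) {
    if (identical(preset, "paper")) return(paper_mixture())
    abort(paste0("unknown preset: ", preset),
          class = "pahrisk_validation_error")
  }
  stopifnot(inherits(spec, "synthesis_spec"))
  if (spec$n_compounds < 1) {
    abort("n_compounds must be at least 1",
          class = "pahrisk_validation_error")
  }
  if (!setequal(names(concern_probs), concern_levels())) {
    abort("concern_probs must name every concern level",
          class = "pahrisk_validation_error")
  }
  set.seed(spec$seed)
  n <- spec$n_compounds
  conc <- exp(runif(n, log(spec$concentration_scale / 1000),
                    log(spec$concentration_scale)))
  conc <- round(sort(conc, decreasing = TRUE), 1)
  mixture_profile(
    tibble::tibble(
      name = sprintf("PAH_%02d", seq_len(n)),
      concentration = conc,
      concentration_sd = round(conc * 0.1, 2),
      is_priority = runif(n) < priority_prob,
      concern_level = sample(concern_levels(), n, replace = TRUE,
                             prob = concern_probs[concern_levels()])
    ),
    source_label = "synthetic"
  )
}

#' Generate synthetic stratified biomarker tables with known intakes
#'
#' Forward-simulates urinary metabolite concentrations from the spec's
#' ground-truth intakes: for each parent and stratum level,
#' `conc = intake * effect * excretion_fraction * body_weight *
#' MW_metabolite / (urine_output * MW_parent)`, optionally multiplied by
#' lognormal noise with median 1 and coefficient of variation `noise_cv`
#' (so geometric means remain unbiased for the truth).
#'
#' @param spec A [synthesis_spec()].
#' @param kinetics Kinetics table covering every parent in
#'   `spec$true_intakes`.
#' @param constants A [population_constants()] list.
#' @param axes Which stratum axes to expand (others are `"all"`).
#' @param n_replicates Records per (parent, stratum) cell.
#' @return Biomarker tibble (see [estimate_population()]) with the
#'   ground-truth per-stratum intakes attached as attribute
#'   `"true_intakes"`.
#' @export
generate_biomarkers <- function(spec, kinetics = default_kinetics(),
                                constants = population_constants(),
                                axes = "smoking_status",
                                n_replicates = 1) {
  stopifnot(inherits(spec, "synthesis_spec"))
  kinetics <- validate_kinetics(kinetics)
  axes <- match.arg(axes, names(stratum_levels), several.ok = TRUE)
  missing_k <- setdiff(names(spec$true_intakes), kinetics$parent)
  if (length(missing_k) > 0) {
    abort(paste0("no kinetics entry for parent(s): ",
                 paste(missing_k, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  set.seed(spec$seed)
  cells <- list(gender = "all", race_ethnicity = "all",
                smoking_status = "all")
  for (axis in axes) cells[[axis]] <- stratum_levels[[axis]]
  grid <- expand.grid(parent = names(spec$true_intakes),
                      gender = cells$gender,
                      race_ethnicity = cells$race_ethnicity,
                      smoking_status = cells$smoking_status,
                      stringsAsFactors = FALSE)
  effect_of <- function(level) {
    f <- spec$stratum_effects[level]
    ifelse(is.na(f), 1, f)
  }
  grid$effect <- effect_of(grid$gender) * effect_of(grid$race_ethnicity) *
    effect_of(grid$smoking_status)
  grid$true_intake <- unname(spec$true_intakes[grid$parent]) * grid$effect
  k <- kinetics[match(grid$parent, kinetics$parent), ]
  grid$metabolite <- k$metabolite
  grid$concentration <- grid$true_intake * k$excretion_fraction *
    constants$body_weight * k$mw_metabolite /
    (constants$daily_urine_output * k$mw_parent)
  out <- grid[rep(seq_len(nrow(grid)), each = n_replicates), ]
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    out$concentration <- out$concentration *
      exp(rnorm(nrow(out), 0, sdlog))
  }
  truth <- tibble::as_tibble(
    grid[c("parent", "gender", "race_ethnicity", "smoking_status",
           "true_intake")]
  )
  result <- tibble::as_tibble(
    out[c("metabolite", "concentration", "gender", "race_ethnicity",
          "smoking_status")]
  )
  attr(result, "true_intakes") <- truth
  result
}

#' Generate a synthetic characterization table
#'
#' Builds a compartment x route table for the given compounds in which
#' total effect factors decrease strictly along `spec$cf_ordering` and
#' intake in every compartment is fish-dominated, with drinking water and
#' produce as the next routes — the qualitative structure expected of
#' water- and soil-emitted PAH mixtures.
#'
#' @param spec A [synthesis_spec()].
#' @param compounds Compound names; defaults to the packaged slope-set
#'   contaminants of concern.
#' @return A validated characterization tibble.
#' @export
generate_characterization <- function(spec,
                                      compounds = names(cancer_slopes("oral"))) {
  stopifnot(inherits(spec, "synthesis_spec"))
  comps <- spec$cf_ordering
  if (length(comps) == 0) {
    abort("cf_ordering must be non-empty",
          class = "pahrisk_validation_error")
  }
  if (anyDuplicated(comps)) {
    abort("duplicate compartments in cf_ordering",
          class = "pahrisk_validation_error")
  }
  set.seed(spec$seed + 1L)
  routes <- default_routes()
  route_share <- c(inhalation = 0.05, drinking_water = 0.15, produce = 0.12,
                   meat_dairy = 0.08, fish = 0.60)
  # positive per-compound weights, normalized; deterministic under seed
  w <- runif(length(compounds), 0.5, 1.5)
  w <- w / sum(w)
  rows <- list()
  for (i in seq_along(comps)) {
    if_total <- 1e-4 * 0.5^(i - 1)       # kg intake per kg emitted
    cc_total <- 2e-6 * 0.5^(i - 1)       # cancer cases per kg emitted
    daly_total <- 2e-5 * 0.5^(i - 1)     # DALY per kg emitted
    for (r in routes) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        compound = compounds,
        compartment = comps[i],
        route = r,
        intake_fraction = if_total * route_share[[r]] * w,
        cancer_cases_per_kg = cc_total * route_share[[r]] * w,
        daly_per_kg = daly_total * route_share[[r]] * w
      )
    }
  }
  characterization_table(dplyr::bind_rows(rows))
}
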