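# Reverse dosimetry: back-calculate daily parent-PAH intake from urinary
# metabolite concentrations,
#
#   intake (ug/kg-day) = conc_urine * urine_output * MW_parent /
#                        (excretion_fraction * body_weight * MW_metabolite)
#
# then stratify by demographic group and rank subpopulations by exposure.

#' Default excretion kinetics for the four biomonitored PAHs
#'
#' One urinary metabolite per parent compound (naphthalene, fluorene,
#' phenanthrene, pyrene) with molecular weights and urinary excretion
#' fractions. These are documented configuration defaults drawn from the
#' biomonitoring literature, not measured ground truth; supply your own
#' table to override.
#'
#' @return Tibble with columns `parent`, `metabolite`, `mw_parent`,
#'   `mw_metabolite`, `excretion_fraction`.
#' @export
default_kinetics <- function() {
  validate_kinetics(readr::read_csv(
    pahrisk_extdata("default_kinetics.csv"),
    col_types = "ccddd", progress = FALSE
  ))
}

validate_kinetics <- function(kinetics) {
  kinetics <- tibble::as_tibble(kinetics)
  required <- c("parent", "metabolite", "mw_parent", "mw_metabolite",
                "excretion_fraction")
  missing_cols <- setdiff(required, names(kinetics))
  if (length(missing_cols) > 0) {
    abort(paste0("kinetics table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pahrisk_schema_error")
  }
  if (any(kinetics$mw_parent <= 0) || any(kinetics$mw_metabolite <= 0)) {
    abort("molecular weights must be positive",
          class = "pahrisk_validation_error")
  }
  if (any(kinetics$excretion_fraction <= 0 |
            kinetics$excretion_fraction > 1)) {
    abort("excretion_fraction must lie in (0, 1]",
          class = "pahrisk_validation_error")
  }
  if (anyDuplicated(kinetics$metabolite)) {
    abort("duplicate metabolite in kinetics table",
          class = "pahrisk_validation_error")
  }
  kinetics
}

#' Population constants for intake back-calculation
#'
#' @param daily_urine_output Standardized adult urine output, L/day.
#' @param body_weight Standardized adult body weight, kg.
#' @return Named list with both constants.
#' @export
population_constants <- function(daily_urine_output = 1.6, body_weight = 80) {
  if (daily_urine_output <= 0 || body_weight <= 0) {
    abort("population constants must be positive",
          class = "pahrisk_validation_error")
  }
  list(daily_urine_output = daily_urine_output, body_weight = body_weight)
}

#' Back-calculate intake from one urinary biomarker measurement
#'
#' @param record Named list or one-row data frame with `metabolite` and
#'   `concentration` (ug/L urine).
#' @param kinetics One-row kinetics table (see [default_kinetics()]) whose
#'   `metabolite` matches the record.
#' @param constants A [population_constants()] list.
#' @return Estimated parent-compound intake, ug/kg-day.
#' @export
#' @examples
#' estimate_intake(
#'   list(metabolite = "m", concentration = 10),
#'   data.frame(parent = "p", metabolite = "m", mw_parent = 1,
#'              mw_metabolite = 1, excretion_fraction = 0.5),
#'   population_constants(1.5, 75)
#' )  # 0.4
estimate_intake <- function(record, kinetics,
                            constants = population_constants()) {
  kinetics <- validate_kinetics(kinetics)
  if (nrow(kinetics) != 1) {
    abort("estimate_intake expects a single kinetics row",
          class = "pahrisk_validation_error")
  }
  record <- as.list(record)
  if (!identical(as.character(record$metabolite), kinetics$metabolite)) {
    abort(paste0("record metabolite '", record$metabolite,
                 "' does not match kinetics metabolite '",
                 kinetics$metabolite, "'"),
          class = "pahrisk_validation_error")
  }
  conc <- as.numeric(record$concentration)
  if (is.na(conc) || conc < 0) {
    abort("concentration must be nonnegative",
          class = "pahrisk_validation_error")
  }
  conc * constants$daily_urine_output * kinetics$mw_parent /
    (kinetics$excretion_fraction * constants$body_weight *
       kinetics$mw_metabolite)
}

validate_biomarkers <- function(biomarkers) {
  biomarkers <- tibble::as_tibble(biomarkers)
  required <- c("metabolite", "concentration", "gender", "race_ethnicity",
                "smoking_status")
  missing_cols <- setdiff(required, names(biomarkers))
  if (length(missing_cols) > 0) {
    abort(paste0("biomarker table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pahrisk_schema_error")
  }
  if (any(biomarkers$concentration < 0)) {
    abort("biomarker concentrations must be nonnegative",
          class = "pahrisk_validation_error")
  }
  for (axis in names(stratum_levels)) {
    ok <- c(stratum_levels[[axis]], "all")
    bad <- setdiff(unique(biomarkers[[axis]]), ok)
    if (length(bad) > 0) {
      abort(paste0("unknown ", axis, " value(s): ",
                   paste(bad, collapse = ", ")),
            class = "pahrisk_validation_error")
    }
  }
  biomarkers
}

#' Estimate stratified population intake from a biomarker table
#'
#' Applies the reverse-dosimetry formula to every record and aggregates to
#' one intake per parent compound and stratum. Replicate records within a
#' stratum are combined by geometric mean by default, matching the
#' geometric-mean reporting convention of population urinary biomarkers.
#'
#' @param biomarkers Tibble with columns `metabolite`, `concentration`
#'   (ug/L), `gender`, `race_ethnicity`, `smoking_status` (stratum axes may
#'   be `"all"`).
#' @param kinetics Kinetics table covering every metabolite present.
#' @param constants A [population_constants()] list.
#' @param aggregate `"geometric_mean"` (default) or `"mean"` for combining
#'   replicate records within a stratum.
#' @param combine_metabolites When several metabolites map to one parent:
#'   `"error"` (default; the packaged configuration is one metabolite per
#'   parent) or `"sum"` to add metabolite-wise intake estimates.
#' @return Tibble with one row per (parent, stratum): `parent`, `gender`,
#'   `race_ethnicity`, `smoking_status`, `intake` (ug/kg-day).
#' @export
estimate_population <- function(biomarkers, kinetics = default_kinetics(),
                                constants = population_constants(),
                                aggregate = c("geometric_mean", "mean"),
                                combine_metabolites = c("error", "sum")) {
  aggregate <- match.arg(aggregate)
  combine_metabolites <- match.arg(combine_metabolites)
  biomarkers <- validate_biomarkers(biomarkers)
  kinetics <- validate_kinetics(kinetics)
  missing_k <- setdiff(unique(biomarkers$metabolite), kinetics$metabolite)
  if (length(missing_k) > 0) {
    abort(paste0("no kinetics entry for metabolite(s): ",
                 paste(missing_k, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  multi <- kinetics$parent[duplicated(kinetics$parent)]
  if (combine_metabolites == "error" &&
      any(kinetics$parent %in% multi & kinetics$metabolite %in%
            biomarkers$metabolite) && length(multi) > 0) {
    present <- kinetics[kinetics$metabolite %in% biomarkers$metabolite, ]
    if (anyDuplicated(present$parent)) {
      abort(paste0("parent(s) with several metabolites present: ",
                   paste(unique(present$parent[duplicated(present$parent)]),
                         collapse = ", "),
                   "; set combine_metabolites = \"sum\""),
            class = "pahrisk_validation_error")
    }
  }
  joined <- dplyr::inner_join(biomarkers, kinetics, by = "metabolite")
  joined$intake <- joined$concentration * constants$daily_urine_output *
    joined$mw_parent /
    (joined$excretion_fraction * constants$body_weight * joined$mw_metabolite)
  agg_fun <- if (aggregate == "geometric_mean") {
    function(x) if (any(x == 0)) 0 else exp(mean(log(x)))
  } else {
    mean
  }
  out <- joined |>
    dplyr::group_by(.data$parent, .data$metabolite, .data$gender,
                    .data$race_ethnicity, .data$smoking_status) |>
    dplyr::summarise(intake = agg_fun(.data$intake), .groups = "drop")
  # metabolite-wise estimates for one parent add (sum mode), else 1:1
  out <- out |>
    dplyr::group_by(.data$parent, .data$gender, .data$race_ethnicity,
                    .data$smoking_status) |>
    dplyr::summarise(intake = sum(.data$intake), .groups = "drop") |>
    dplyr::arrange(.data$parent, .data$gender, .data$race_ethnicity,
                   .data$smoking_status)
  out
}

#' Rank strata along one demographic axis by total intake
#'
#' @param intakes Output of [estimate_population()].
#' @param axis `"gender"`, `"race_ethnicity"` or `"smoking_status"`.
#' @return Tibble of `level` and `total_intake` (summed over parents and the
#'   other axes), sorted descending; ties broken alphabetically. Rows whose
#'   value on the axis is `"all"` are excluded from the ranking.
#' @export
rank_strata <- function(intakes, axis) {
  if (length(axis) != 1 || !axis %in% names(stratum_levels)) {
    abort(paste0("unknown stratum axis: ", paste(axis, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  intakes <- tibble::as_tibble(intakes)
  intakes <- intakes[intakes[[axis]] != "all", ]
  if (nrow(intakes) == 0) {
    abort(paste0("no rows stratified along ", axis),
          class = "pahrisk_validation_error")
  }
  totals <- intakes |>
    dplyr::group_by(level = .data[[axis]]) |>
    dplyr::summarise(total_intake = sum(.data$intake), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_intake), .data$level)
  totals
}
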