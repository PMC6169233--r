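# Compartment x route intake fractions and health effect factors for the
# mixture: pooling over compounds, route apportionment of intake, and
# per-compartment cancer-case / DALY summaries. The multimedia fate model
# that produces such records is upstream of this package; any table in the
# schema below is accepted.

default_compartments <- function() {
  c("household_indoor_air", "fresh_water", "sea_water",
    "natural_soil", "agricultural_soil")
}

default_routes <- function() {
  c("inhalation", "drinking_water", "produce", "meat_dairy", "fish")
}

#' Validate a characterization table
#'
#' A characterization table has one record per (compound, compartment,
#' route): the intake fraction (kg taken in by the population per kg
#' emitted to the compartment) and the health effect factors (excess cancer
#' cases and disability-adjusted life years per kg emitted). Compartment
#' and route vocabularies are free-form so site-specific compartments can
#' be added.
#'
#' @param records Data frame with columns `compound`, `compartment`,
#'   `route`, `intake_fraction`, `cancer_cases_per_kg`, `daly_per_kg`.
#' @return The validated tibble.
#' @export
characterization_table <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("compound", "compartment", "route", "intake_fraction",
                "cancer_cases_per_kg", "daly_per_kg")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("characterization table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pahrisk_schema_error")
  }
  num <- c("intake_fraction", "cancer_cases_per_kg", "daly_per_kg")
  for (col in num) {
    if (any(!is.finite(records[[col]]) | records[[col]] < 0)) {
      abort(paste0(col, " must be nonnegative and finite"),
            class = "pahrisk_validation_error")
    }
  }
  key <- paste(records$compound, records$compartment, records$route,
               sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (compound, compartment, route) record",
          class = "pahrisk_validation_error")
  }
  records[required]
}

#' Read a characterization table from CSV
#'
#' @param path CSV with header
#'   `compound,compartment,route,intake_fraction,cancer_cases_per_kg,daly_per_kg`.
#' @return Validated characterization tibble.
#' @export
load_characterization <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("characterization file not found: ", path),
          class = "pahrisk_schema_error")
  }
  characterization_table(readr::read_csv(path, col_types = "cccddd",
                                         progress = FALSE))
}

check_compounds_present <- function(table, compounds) {
  missing_c <- setdiff(compounds, unique(table$compound))
  if (length(missing_c) > 0) {
    abort(paste0("compound(s) absent from characterization table: ",
                 paste(missing_c, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
}

#' Pool characterization records over a compound set
#'
#' Restricts the table to the requested compounds and sums intake fractions
#' and effect factors per (compartment, route), yielding records for the
#' mixture as a whole (compound label `"mixture"`).
#'
#' @param table Characterization tibble (see [characterization_table()]).
#' @param compounds Character vector of compound names, all present.
#' @return Pooled characterization tibble.
#' @export
pool_mixture <- function(table, compounds) {
  table <- characterization_table(table)
  check_compounds_present(table, compounds)
  table |>
    dplyr::filter(.data$compound %in% compounds) |>
    dplyr::group_by(.data$compartment, .data$route) |>
    dplyr::summarise(
      intake_fraction = sum(.data$intake_fraction),
      cancer_cases_per_kg = sum(.data$cancer_cases_per_kg),
      daly_per_kg = sum(.data$daly_per_kg),
      .groups = "drop"
    ) |>
    dplyr::mutate(compound = "mixture", .before = 1) |>
    characterization_table()
}

#' Apportion a compartment's intake across exposure routes
#'
#' @param table Characterization tibble (typically pooled).
#' @param compartment Compartment name with positive total intake.
#' @return Tibble of `route` and `share`; shares sum to 1.
#' @export
route_apportionment <- function(table, compartment) {
  table <- characterization_table(table)
  rows <- table[table$compartment == compartment, ]
  if (nrow(rows) == 0) {
    abort(paste0("compartment not in table: ", compartment),
          class = "pahrisk_validation_error")
  }
  totals <- rows |>
    dplyr::group_by(.data$route) |>
    dplyr::summarise(intake = sum(.data$intake_fraction), .groups = "drop")
  total <- sum(totals$intake)
  if (total <= 0) {
    abort(paste0("compartment ", compartment,
                 " has zero total intake; apportionment undefined"),
          class = "pahrisk_validation_error")
  }
  tibble::tibble(route = totals$route, share = totals$intake / total) |>
    dplyr::arrange(dplyr::desc(.data$share), .data$route)
}

#' Pooled health effects per environmental compartment
#'
#' Sums intake fractions and effect factors for the pooled mixture over all
#' routes within each compartment, ordered by decreasing cancer effect.
#'
#' @param table Characterization tibble.
#' @param compounds Compound names to pool.
#' @return Tibble of `compartment`, `intake_fraction`,
#'   `cancer_cases_per_kg`, `daly_per_kg`, sorted by `cancer_cases_per_kg`
#'   descending.
#' @export
effects_by_compartment <- function(table, compounds) {
  pooled <- pool_mixture(table, compounds)
  pooled |>
    dplyr::group_by(.data$compartment) |>
    dplyr::summarise(
      intake_fraction = sum(.data$intake_fraction),
      cancer_cases_per_kg = sum(.data$cancer_cases_per_kg),
      daly_per_kg = sum(.data$daly_per_kg),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$cancer_cases_per_kg),
                   .data$compartment)
}
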