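# Mixture profiles: per-compound sediment concentrations annotated with EPA
# 16-priority-list membership and an ordered structure-activity carcinogenic
# concern level.

new_mixture_profile <- function(compounds, source_label) {
  structure(
    list(compounds = compounds, source_label = source_label),
    class = "mixture_profile"
  )
}

#' Construct a PAH mixture profile
#'
#' A mixture profile holds one row per compound: its sediment concentration
#' (ng/mL), the measurement standard deviation, whether it is on the EPA list
#' of 16 priority PAHs, and its carcinogenic concern level from
#' structure-activity screening (see [concern_levels()]).
#'
#' @param compounds A data frame with columns `name`, `concentration`,
#'   `concentration_sd`, `is_priority` (logical) and `concern_level`
#'   (character or factor drawn from [concern_levels()]).
#' @param source_label Free-text provenance label for the profile.
#' @return A `mixture_profile` object.
#' @export
#' @examples
#' mixture_profile(data.frame(
#'   name = "Benzo(a)pyrene", concentration = 44.3, concentration_sd = 2.4,
#'   is_priority = TRUE, concern_level = "high"
#' ))
mixture_profile <- function(compounds, source_label = "user") {
  required <- c("name", "concentration", "concentration_sd",
                "is_priority", "concern_level")
  missing_cols <- setdiff(required, names(compounds))
  if (length(missing_cols) > 0) {
    abort(paste0("mixture table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pahrisk_schema_error")
  }
  compounds <- tibble::as_tibble(compounds)[required]
  if (nrow(compounds) < 1) {
    abort("a mixture profile needs at least one compound",
          class = "pahrisk_validation_error")
  }
  if (anyDuplicated(compounds$name)) {
    dup <- unique(compounds$name[duplicated(compounds$name)])
    abort(paste0("duplicate compound name(s): ", paste(dup, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  bad <- which(!is.finite(compounds$concentration) | compounds$concentration < 0)
  if (length(bad) > 0) {
    abort(paste0("negative or non-finite concentration in row(s): ",
                 paste(bad, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  bad_sd <- which(!is.finite(compounds$concentration_sd) |
                    compounds$concentration_sd < 0)
  if (length(bad_sd) > 0) {
    abort(paste0("negative or non-finite standard deviation in row(s): ",
                 paste(bad_sd, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  compounds$is_priority <- as.logical(compounds$is_priority)
  if (anyNA(compounds$is_priority)) {
    abort("is_priority must be TRUE or FALSE for every compound",
          class = "pahrisk_validation_error")
  }
  compounds$concern_level <- parse_concern(compounds$concern_level)
  new_mixture_profile(compounds, source_label)
}

# map raw concern strings onto the ordered factor; blanks -> none
parse_concern <- function(x) {
  x <- as.character(x)
  x <- tolower(trimws(x))
  x[is.na(x) | x == ""] <- "none"
  unknown <- setdiff(unique(x), concern_levels())
  if (length(unknown) > 0) {
    abort(paste0("unknown concern level(s): ", paste(unknown, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  factor(x, levels = concern_levels(), ordered = TRUE)
}

parse_priority_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x)] <- ""
  truthy <- c("+", "true", "t", "yes", "y", "1")
  falsy <- c("", "-", "false", "f", "no", "n", "0")
  unknown <- setdiff(unique(x), c(truthy, falsy))
  if (length(unknown) > 0) {
    abort(paste0("uninterpretable priority flag(s): ",
                 paste(unknown, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  x %in% truthy
}

#' Read a mixture profile from CSV
#'
#' Expects a UTF-8 CSV with header
#' `name,concentration_ng_ml,sd_ng_ml,epa_priority,oncologic_level`.
#' An empty priority cell means "not on the priority list"; an empty concern
#' cell means no ranking was carried into results (`none`).
#'
#' @param path Path to the CSV file.
#' @param source_label Provenance label; defaults to the file name.
#' @return A [mixture_profile()] object.
#' @export
load_mixture <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("mixture file not found: ", path),
          class = "pahrisk_schema_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("name", "concentration_ng_ml", "sd_ng_ml",
                "epa_priority", "oncologic_level")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("mixture CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pahrisk_schema_error")
  }
  mixture_profile(
    tibble::tibble(
      name = raw$name,
      concentration = as.numeric(raw$concentration_ng_ml),
      concentration_sd = as.numeric(raw$sd_ng_ml),
      is_priority = parse_priority_flag(raw$epa_priority),
      concern_level = raw$oncologic_level
    ),
    source_label = source_label
  )
}

#' Write a mixture profile to CSV
#'
#' Inverse of [load_mixture()]: writes the
#' `name,concentration_ng_ml,sd_ng_ml,epa_priority,oncologic_level` schema so
#' that a load/write/load round trip preserves all fields.
#'
#' @param profile A [mixture_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mixture <- function(profile, path) {
  stopifnot(inherits(profile, "mixture_profile"))
  cmp <- profile$compounds
  out <- tibble::tibble(
    name = cmp$name,
    concentration_ng_ml = cmp$concentration,
    sd_ng_ml = cmp$concentration_sd,
    epa_priority = ifelse(cmp$is_priority, "+", ""),
    oncologic_level = ifelse(cmp$concern_level == "none", "",
                             as.character(cmp$concern_level))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' The packaged Superfund sediment mixture profile
#'
#' The 35-compound PAH mixture measured in contaminated estuarine sediment
#' at a wood-treatment Superfund site, shipped with the package: per-compound
#' concentrations (ng/mL) with standard deviations, EPA priority-list flags,
#' and structure-activity carcinogenic concern levels. The
#' 3-Methylcholanthrene row is retained at a concentration of zero.
#'
#' @return A [mixture_profile()] with 35 compounds.
#' @export
#' @examples
#' mix <- paper_mixture()
#' count_priority(mix)
paper_mixture <- function() {
  load_mixture(pahrisk_extdata("table2_mixture.csv"),
               source_label = "superfund_sediment")
}

#' Count EPA priority PAHs in a mixture
#'
#' @param profile A [mixture_profile()].
#' @return Number of compounds flagged as members of the EPA 16-priority list.
#' @export
count_priority <- function(profile) {
  stopifnot(inherits(profile, "mixture_profile"))
  sum(profile$compounds$is_priority)
}

#' Count compounds at or above a carcinogenic concern level
#'
#' @param profile A [mixture_profile()].
#' @param threshold One of [concern_levels()]. The default, `low-moderate`,
#'   is the package's working definition of "carcinogenic concern".
#' @return Number of compounds whose concern level is `>= threshold` in the
#'   ordered vocabulary.
#' @export
#' @examples
#' count_concern(paper_mixture())            # 11
#' count_concern(paper_mixture(), "none")    # every compound
count_concern <- function(profile, threshold = "low-moderate") {
  stopifnot(inherits(profile, "mixture_profile"))
  if (length(threshold) != 1 || !threshold %in% concern_levels()) {
    abort(paste0("unknown concern threshold: ", paste(threshold, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  thr <- factor(threshold, levels = concern_levels(), ordered = TRUE)
  sum(profile$compounds$concern_level >= thr)
}

#' Summarize a mixture profile
#'
#' @param profile A [mixture_profile()].
#' @param k Number of top compounds (by concentration, ties broken
#'   alphabetically) to report.
#' @return A list with `total_concentration` (ng/mL), `n_compounds`,
#'   `top_compounds` (tibble of the k largest), and `concern_counts`
#'   (tibble of compounds per concern level).
#' @export
summarize_mixture <- function(profile, k = 5) {
  stopifnot(inherits(profile, "mixture_profile"))
  cmp <- profile$compounds
  ord <- order(-cmp$concentration, cmp$name)
  top <- cmp[ord, c("name", "concentration")][seq_len(min(k, nrow(cmp))), ]
  concern_counts <- tibble::tibble(
    concern_level = concern_levels(),
    n = as.integer(table(cmp$concern_level)[concern_levels()])
  )
  list(
    total_concentration = sum(cmp$concentration),
    n_compounds = nrow(cmp),
    n_priority = count_priority(profile),
    top_compounds = top,
    concern_counts = concern_counts
  )
}

#' @export
print.mixture_profile <- function(x, ...) {
  cat("<mixture_profile> ", nrow(x$compounds), " compounds (",
      x$source_label, ")\n", sep = "")
  cat("  total concentration: ",
      format(sum(x$compounds$concentration)), " ng/mL\n", sep = "")
  cat("  EPA priority PAHs:   ", count_priority(x), "\n", sep = "")
  cat("  concern >= low-moderate: ", count_concern(x), "\n", sep = "")
  invisible(x)
}
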