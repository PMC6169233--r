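# Deterministic exposure and excess-lifetime-cancer-risk equations for direct
# oral and dermal contact with contaminated sediment.
#
#   CDI      = CS * IR_S * FI * EF * ED * CF / (BW * AT)        [oral]
#   DA_event = CS * CF * AF * ABSd                              [dermal]
#   DAD      = DA_event * EF * ED * EV * SA / (BW * AT)         [dermal]
#   risk     = exposure * sum_c CSF_c * ADAF
#
# Units: CS mg/kg sediment; IR_S mg/day; EF days/yr; ED yr; CF kg/mg (1e-6);
# BW kg; AT days; AF mg/cm2-day; SA cm2; CSF (mg/kg-day)^-1.

scenario_fields <- function(route) {
  shared <- c("CS", "CF", "AT", "ADAF", "BW", "EF", "ED")
  if (route == "oral") c(shared, "IR_S", "FI")
  else c(shared, "AF", "ABSd", "SA", "EV")
}

#' Construct an exposure scenario
#'
#' Bundles one receptor group and exposure route with every exposure factor
#' the sediment-contact equations need. Numeric fields may be vectors of a
#' common length, in which case the risk equations evaluate element-wise
#' (this is how the Monte Carlo engine drives them).
#'
#' @param group One of [exposure_groups()].
#' @param route `"oral"` or `"dermal"`.
#' @param params Named list or vector of exposure factors. Oral scenarios
#'   need `CS, CF, AT, ADAF, BW, EF, ED, IR_S, FI`; dermal scenarios need
#'   `CS, CF, AT, ADAF, BW, EF, ED, AF, ABSd, SA, EV`.
#' @param validate `"strict"` (all factors strictly positive; the default)
#'   or `"relaxed"` (zeros permitted, for analytic edge cases).
#' @return An `exposure_scenario` object.
#' @export
#' @examples
#' table1_scenario("adult_trespasser", "oral")
exposure_scenario <- function(group, route, params,
                              validate = c("strict", "relaxed")) {
  group <- match.arg(group, exposure_groups())
  route <- match.arg(route, exposure_routes())
  validate <- match.arg(validate)
  params <- as.list(params)
  fields <- scenario_fields(route)
  missing_f <- setdiff(fields, names(params))
  if (length(missing_f) > 0) {
    abort(paste0(route, " scenario is missing factor(s): ",
                 paste(missing_f, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  params <- params[fields]
  lens <- vapply(params, length, integer(1))
  if (any(lens < 1) || length(setdiff(unique(lens), 1L)) > 1) {
    abort("scenario factors must be length 1 or share one common length",
          class = "pahrisk_validation_error")
  }
  for (f in fields) {
    v <- as.numeric(params[[f]])
    if (anyNA(v) || any(!is.finite(v))) {
      abort(paste0("factor ", f, " contains non-finite values"),
            class = "pahrisk_validation_error")
    }
    lower_ok <- if (validate == "strict") all(v > 0) else all(v >= 0)
    if (!lower_ok) {
      abort(paste0("factor ", f, " must be ",
                   if (validate == "strict") "strictly positive"
                   else "nonnegative"),
            class = "pahrisk_validation_error")
    }
    if (f %in% c("FI", "ABSd") && any(v > 1)) {
      abort(paste0("fraction ", f, " must lie in (0, 1]"),
            class = "pahrisk_validation_error")
    }
    params[[f]] <- v
  }
  structure(list(group = group, route = route, params = params,
                 validate = validate),
            class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat("<exposure_scenario> ", x$group, ", ", x$route, " route\n", sep = "")
  p <- vapply(x$params, function(v) format(v[1]), character(1))
  cat(paste0("  ", names(p), " = ", p, collapse = "\n"), "\n")
  invisible(x)
}

# Table 1 parameterization -------------------------------------------------

#' Packaged exposure-factor distributions
#'
#' Returns the packaged table of exposure-factor means and half-widths for
#' one receptor group and route: the central values used by the
#' deterministic equations and the `mean +/- half_width` uniform ranges the
#' Monte Carlo engine samples. Randomized factors carry `kind = "uniform"`
#' with half-widths equal to 25% of the mean; factors held constant
#' (sediment concentration, conversion factor, averaging time, age
#' adjustment, ingested/absorbed fractions, event frequency) are
#' `kind = "fixed"`.
#'
#' @param group One of [exposure_groups()].
#' @param route `"oral"` or `"dermal"`.
#' @return A tibble with columns `symbol`, `mean`, `half_width`, `kind`.
#' @export
table1_distributions <- function(group, route) {
  group <- match.arg(group, exposure_groups())
  route <- match.arg(route, exposure_routes())
  tab <- readr::read_csv(pahrisk_extdata("table1_parameters.csv"),
                         col_types = readr::cols(
                           symbol = "c", group = "c", route = "c",
                           mean = "d", half_width = "d", kind = "c"
                         ), progress = FALSE)
  keep <- (tab$group %in% c("all", group)) & (tab$route %in% c("both", route))
  tab <- tab[keep, c("symbol", "mean", "half_width", "kind")]
  ord <- match(tab$symbol, scenario_fields(route))
  tab[order(ord), ]
}

#' Build an exposure scenario from the packaged central values
#'
#' @inheritParams table1_distributions
#' @param validate Passed to [exposure_scenario()].
#' @return An [exposure_scenario()] at the packaged mean exposure factors.
#' @export
table1_scenario <- function(group, route, validate = "strict") {
  dist <- table1_distributions(group, route)
  exposure_scenario(group, route,
                    params = setNames(as.list(dist$mean), dist$symbol),
                    validate = validate)
}

# cancer slope sets ---------------------------------------------------------

#' Cancer slope factor sets
#'
#' A cancer slope set maps each contaminant of concern to its cancer slope
#' factor, `(mg/kg-day)^-1`, for one exposure route. `cancer_slopes()`
#' returns the packaged set: the seven sediment PAH contaminants of concern
#' with their oral or dermal slope factors.
#'
#' @param compounds Character vector of compound names.
#' @param csf Numeric vector of slope factors, same length, all positive.
#' @param route `"oral"` or `"dermal"`.
#' @return A `cancer_slope_set`: named numeric vector with a `route`
#'   attribute.
#' @export
#' @examples
#' sum(cancer_slopes("oral"))   # 16.8703
cancer_slope_set <- function(compounds, csf, route) {
  route <- match.arg(route, exposure_routes())
  if (length(compounds) == 0) {
    abort("a cancer slope set needs at least one compound",
          class = "pahrisk_validation_error")
  }
  if (length(compounds) != length(csf)) {
    abort("compounds and csf must have equal length",
          class = "pahrisk_validation_error")
  }
  if (anyDuplicated(compounds)) {
    abort("duplicate compound in slope set",
          class = "pahrisk_validation_error")
  }
  if (any(!is.finite(csf) | csf <= 0)) {
    abort("cancer slope factors must be strictly positive",
          class = "pahrisk_validation_error")
  }
  structure(setNames(as.numeric(csf), compounds), route = route,
            class = "cancer_slope_set")
}

#' @rdname cancer_slope_set
#' @export
cancer_slopes <- function(route = c("oral", "dermal")) {
  route <- match.arg(route)
  tab <- readr::read_csv(pahrisk_extdata("slope_factors.csv"),
                         col_types = "ccd", progress = FALSE)
  tab <- tab[tab$route == route, ]
  cancer_slope_set(tab$compound, tab$csf, route)
}

# exposure equations ---------------------------------------------------------

check_route <- function(s, wanted) {
  stopifnot(inherits(s, "exposure_scenario"))
  if (s$route != wanted) {
    abort(paste0("scenario route is ", s$route, "; this equation is for the ",
                 wanted, " route"),
          class = "pahrisk_route_error")
  }
}

#' Chronic daily intake (oral route)
#'
#' `CDI = CS * IR_S * FI * EF * ED * CF / (BW * AT)`, in mg/kg-day.
#'
#' @param s An oral-route [exposure_scenario()].
#' @return Numeric vector of chronic daily intake values, mg/kg-day.
#' @export
compute_cdi <- function(s) {
  check_route(s, "oral")
  p <- s$params
  p$CS * p$IR_S * p$FI * p$EF * p$ED * p$CF / (p$BW * p$AT)
}

#' Dermal absorbed dose per event
#'
#' `DA_event = CS * CF * AF * ABSd`, in mg/cm2-event.
#'
#' @param s A dermal-route [exposure_scenario()].
#' @return Numeric vector, mg/cm2-event.
#' @export
compute_da_event <- function(s) {
  check_route(s, "dermal")
  p <- s$params
  p$CS * p$CF * p$AF * p$ABSd
}

#' Dermal absorbed dose
#'
#' `DAD = DA_event * EF * ED * EV * SA / (BW * AT)`, in mg/kg-day.
#'
#' @param s A dermal-route [exposure_scenario()].
#' @return Numeric vector, mg/kg-day.
#' @export
compute_dad <- function(s) {
  check_route(s, "dermal")
  p <- s$params
  compute_da_event(s) * p$EF * p$ED * p$EV * p$SA / (p$BW * p$AT)
}

#' Excess lifetime cancer risk for a scenario
#'
#' Multiplies route-appropriate exposure (CDI for oral, DAD for dermal) by
#' the summed hazard `sum_c CSF_c * ADAF` over the slope-set compounds.
#'
#' Two concentration conventions are supported. In the default shared mode
#' the scenario's single `CS` — the total sediment concentration of the
#' slope-set compounds — drives the exposure term and hazards are summed
#' over it. In per-compound mode, `cs_by_compound` supplies one sediment
#' concentration per slope-set compound and per-compound risks
#' `exposure(CS_c) * CSF_c * ADAF` are summed.
#'
#' @param s An [exposure_scenario()].
#' @param slopes A [cancer_slope_set()] for the same route.
#' @param cs_by_compound Optional named numeric vector of per-compound
#'   sediment concentrations (mg/kg) covering every slope-set compound;
#'   switches on per-compound mode.
#' @return Numeric vector of unitless excess lifetime cancer risk.
#' @export
#' @examples
#' s <- table1_scenario("adult_trespasser", "oral")
#' compute_risk(s, cancer_slopes("oral"))    # ~3.74e-8
compute_risk <- function(s, slopes, cs_by_compound = NULL) {
  stopifnot(inherits(s, "exposure_scenario"))
  if (!inherits(slopes, "cancer_slope_set")) {
    abort("slopes must be a cancer_slope_set",
          class = "pahrisk_validation_error")
  }
  if (attr(slopes, "route") != s$route) {
    abort(paste0("slope set is for the ", attr(slopes, "route"),
                 " route but scenario is ", s$route),
          class = "pahrisk_route_error")
  }
  exposure <- if (s$route == "oral") compute_cdi(s) else compute_dad(s)
  adaf <- s$params$ADAF
  if (is.null(cs_by_compound)) {
    return(exposure * sum(slopes) * adaf)
  }
  missing_cs <- setdiff(names(slopes), names(cs_by_compound))
  if (length(missing_cs) > 0) {
    abort(paste0("cs_by_compound missing: ",
                 paste(missing_cs, collapse = ", ")),
          class = "pahrisk_validation_error")
  }
  # exposure is linear in CS, so scale the shared-CS exposure per compound
  per_unit_cs <- exposure / s$params$CS
  cs <- cs_by_compound[names(slopes)]
  per_unit_cs * sum(cs * unclass(slopes)) * adaf
}
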