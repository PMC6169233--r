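# Monte Carlo propagation of exposure-factor uncertainty through the risk
# equations. Randomized factors are drawn independently and uniformly on
# [mean - half_width, mean + half_width]; the half-widths in the packaged
# configuration are 25% of each mean. 10,000 iterations per group/route is
# the reference configuration.

randomized_symbols <- function(route) {
  if (route == "oral") c("IR_S", "EF", "ED", "BW")
  else c("EF", "ED", "AF", "SA", "BW")
}

#' Build a Monte Carlo simulation configuration
#'
#' @param group One of [exposure_groups()].
#' @param route `"oral"` or `"dermal"`.
#' @param n_iterations Number of iterations (default 10000).
#' @param seed Integer RNG seed recorded in every downstream summary.
#' @param distributions Tibble with columns `symbol`, `mean`, `half_width`,
#'   `kind` (`"fixed"` or `"uniform"`). Defaults to the packaged
#'   [table1_distributions()] for the group and route.
#' @param family Sampling family for randomized factors: `"uniform"` (the
#'   default; the unique distribution determined by a minimum and maximum
#'   alone) or `"truncnorm"` (normal with `sd = half_width/2`, truncated to
#'   the same support).
#' @return A `simulation_config` object.
#' @export
#' @examples
#' simulation_config("adult_trespasser", "oral", seed = 1)
simulation_config <- function(group, route, n_iterations = 10000, seed = 1,
                              distributions = NULL,
                              family = c("uniform", "truncnorm")) {
  group <- match.arg(group, exposure_groups())
  route <- match.arg(route, exposure_routes())
  family <- match.arg(family)
  if (length(n_iterations) != 1 || n_iterations < 1 ||
      n_iterations != round(n_iterations)) {
    abort("n_iterations must be a positive integer",
          class = "pahrisk_validation_error")
  }
  if (is.null(distributions)) {
    distributions <- table1_distributions(group, route)
  }
  distributions <- tibble::as_tibble(distributions)
  needed <- c("symbol", "mean", "half_width", "kind")
  if (!all(needed %in% names(distributions))) {
    abort("distributions needs columns symbol, mean, half_width, kind",
          class = "pahrisk_config_error")
  }
  if (anyDuplicated(distributions$symbol)) {
    abort("a symbol appears twice in the distribution table",
          class = "pahrisk_config_error")
  }
  unknown <- setdiff(distributions$symbol, scenario_fields(route))
  if (length(unknown) > 0) {
    abort(paste0("distribution references unknown symbol(s): ",
                 paste(unknown, collapse = ", ")),
          class = "pahrisk_config_error")
  }
  with(distributions, {
    if (any(half_width < 0)) {
      abort("half_width must be nonnegative", class = "pahrisk_config_error")
    }
    if (any(kind == "uniform" & half_width >= mean)) {
      abort("half_width must be smaller than the mean (positive support)",
            class = "pahrisk_config_error")
    }
    if (any(kind == "fixed" & half_width != 0)) {
      abort("fixed parameters must have half_width 0",
            class = "pahrisk_config_error")
    }
  })
  missing_rand <- setdiff(randomized_symbols(route),
                          distributions$symbol)
  if (length(missing_rand) > 0) {
    abort(paste0("no distribution given for randomized symbol(s): ",
                 paste(missing_rand, collapse = ", ")),
          class = "pahrisk_config_error")
  }
  structure(list(group = group, route = route,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 distributions = distributions, family = family),
            class = "simulation_config")
}

draw_factor <- function(n, mean, half_width, family) {
  if (half_width == 0) return(rep(mean, n))
  a <- mean - half_width
  b <- mean + half_width
  if (family == "uniform") {
    runif(n, a, b)
  } else {
    s <- half_width / 2
    lo <- stats::pnorm(a, mean, s)
    hi <- stats::pnorm(b, mean, s)
    stats::qnorm(runif(n, lo, hi), mean, s)
  }
}

#' Sample exposure scenarios from a simulation configuration
#'
#' Draws `n` independent realizations of every randomized exposure factor
#' (uniform on its `mean +/- half_width` range by default) and carries fixed
#' factors over from the base scenario unchanged. Factors are drawn in the
#' order the configuration lists them, so a given seed reproduces the same
#' draws.
#'
#' @param config A [simulation_config()].
#' @param base An [exposure_scenario()] supplying the fixed factors.
#' @param n Number of realizations (default: one).
#' @param seed Optional seed set before drawing; `NULL` leaves the RNG state
#'   alone (as when [simulate_risk()] has already seeded it).
#' @return An [exposure_scenario()] whose randomized factors are length-`n`
#'   vectors.
#' @export
sample_scenario <- function(config, base, n = 1, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(base, "exposure_scenario"))
  if (config$route != base$route || config$group != base$group) {
    abort("config and base scenario disagree on group or route",
          class = "pahrisk_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  params <- base$params
  d <- config$distributions
  for (i in seq_len(nrow(d))) {
    if (d$kind[i] == "fixed") next
    params[[d$symbol[i]]] <- draw_factor(n, d$mean[i], d$half_width[i],
                                         config$family)
  }
  exposure_scenario(base$group, base$route, params,
                    validate = base$validate)
}

#' Simulate the cancer-risk distribution for one group and route
#'
#' Runs `n_iterations` Monte Carlo iterations: each iteration draws the
#' randomized exposure factors, evaluates the route's exposure equation, and
#' multiplies by the summed hazard over the slope-set compounds.
#'
#' @param config A [simulation_config()].
#' @param base Base [exposure_scenario()]; defaults to the packaged central
#'   values for the config's group and route.
#' @param slopes A [cancer_slope_set()]; defaults to the packaged set for
#'   the route.
#' @return Numeric vector of `n_iterations` excess lifetime cancer risk
#'   values, with the seed attached as attribute `seed`.
#' @export
#' @examples
#' r <- simulate_risk(simulation_config("adult_trespasser", "oral",
#'                                      n_iterations = 100, seed = 7))
#' summarize_distribution(r)
simulate_risk <- function(config,
                          base = table1_scenario(config$group, config$route),
                          slopes = cancer_slopes(config$route)) {
  scen <- sample_scenario(config, base, n = config$n_iterations,
                          seed = config$seed)
  risks <- compute_risk(scen, slopes)
  if (length(risks) == 1 && config$n_iterations > 1) {
    # every factor fixed: the distribution degenerates to the point estimate
    risks <- rep(risks, config$n_iterations)
  }
  attr(risks, "seed") <- config$seed
  risks
}

#' Descriptive statistics of a simulated risk distribution
#'
#' @param risks Non-empty numeric vector of risk values.
#' @param ci_method `"normal"` for the normal-approximation 95% CI of the
#'   mean (`mean +/- 1.96 sd/sqrt(n)`), or `"bootstrap"` for a percentile
#'   bootstrap.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return One-row tibble: `n`, `mean`, `sd`, `minimum`, `maximum`,
#'   `median`, `percentile_2.5`, `percentile_97.5`, `ci95_lower`,
#'   `ci95_upper` (of the mean), and adjusted Fisher-Pearson `skewness`.
#'   Percentiles use linear interpolation.
#' @export
summarize_distribution <- function(risks, ci_method = c("normal", "bootstrap"),
                                   n_boot = 2000) {
  ci_method <- match.arg(ci_method)
  risks <- as.numeric(risks)
  if (length(risks) == 0) {
    abort("cannot summarize an empty risk collection",
          class = "pahrisk_validation_error")
  }
  n <- length(risks)
  m <- mean(risks)
  s <- if (n > 1) sd(risks) else 0
  if (ci_method == "normal") {
    half <- 1.96 * s / sqrt(n)
    ci <- c(m - half, m + half)
  } else {
    boots <- vapply(seq_len(n_boot),
                    function(i) mean(risks[sample.int(n, n, replace = TRUE)]),
                    numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
  }
  # adjusted Fisher-Pearson sample skewness
  skew <- if (n >= 3 && s > 0) {
    g1 <- mean((risks - m)^3) / (mean((risks - m)^2))^1.5
    g1 * sqrt(n * (n - 1)) / (n - 2)
  } else {
    NA_real_
  }
  q <- unname(quantile(risks, c(0.025, 0.5, 0.975), type = 7))
  tibble::tibble(
    n = n, mean = m, sd = s,
    minimum = min(risks), maximum = max(risks), median = q[2],
    percentile_2.5 = q[1], percentile_97.5 = q[3],
    ci95_lower = ci[1], ci95_upper = ci[2],
    skewness = skew
  )
}

#' Bin a risk distribution into a histogram table
#'
#' @param risks Non-empty numeric vector.
#' @param bins Number of equal-width bins covering `[min, max]`.
#' @param path Optional CSV path for the bin table.
#' @param plot_path Optional path (`.png` or `.pdf`) for a histogram figure.
#' @return Tibble with `bin_lower`, `bin_upper`, `count`; counts sum to
#'   `length(risks)`.
#' @export
export_histogram <- function(risks, bins = 20, path = NULL, plot_path = NULL) {
  risks <- as.numeric(risks)
  if (length(risks) == 0) {
    abort("cannot bin an empty risk collection",
          class = "pahrisk_validation_error")
  }
  if (length(bins) != 1 || bins < 1 || bins != round(bins)) {
    abort("bins must be a positive integer",
          class = "pahrisk_validation_error")
  }
  lo <- min(risks)
  hi <- max(risks)
  if (lo == hi) {
    out <- tibble::tibble(bin_lower = lo, bin_upper = hi,
                          count = length(risks))
  } else {
    breaks <- seq(lo, hi, length.out = bins + 1)
    idx <- cut(risks, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    out <- tibble::tibble(
      bin_lower = breaks[-length(breaks)],
      bin_upper = breaks[-1],
      count = tabulate(idx, nbins = bins)
    )
  }
  if (!is.null(path)) readr::write_csv(out, path, progress = FALSE)
  if (!is.null(plot_path)) {
    g <- ggplot2::ggplot(out) +
      ggplot2::geom_rect(ggplot2::aes(
        xmin = .data$bin_lower, xmax = .data$bin_upper,
        ymin = 0, ymax = .data$count
      ), fill = "steelblue", colour = "white") +
      ggplot2::labs(x = "excess lifetime cancer risk", y = "iterations") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(plot_path, g, width = 6, height = 4)
  }
  out
}
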