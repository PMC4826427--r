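#' Default study windows for the five contributing countries
#'
#' Calendar windows of register coverage, as half-open decimal-year
#' intervals `[start, end)`: Australia 2000-2008, Denmark 1995-2012,
#' Finland 1972-2010, Scotland 1995-2011 and Sweden 1987-2012
#' (end years inclusive, so e.g. 2000-2008 is `[2000, 2009)`).
#'
#' @return named list of length-2 numeric vectors `c(start, end)`.
#' @export
country_windows <- function() {
  list(
    AU = c(2000, 2009),
    DK = c(1995, 2013),
    FI = c(1972, 2011),
    SC = c(1995, 2012),
    SE = c(1987, 2013)
  )
}

#' Diabetes-duration bands
#'
#' The duration timescale is cut at 0, 1, 2, 5, 10, 15 and 30 years
#' since diabetes diagnosis, giving seven half-open bands
#' `[0,1), [1,2), [2,5), [5,10), [10,15), [15,30), [30,Inf)`.
#'
#' @param cuts increasing numeric cut points starting at 0.
#' @return object of class `duration_bands`: list with `cuts` and
#'   character `labels` (one per band).
#' @export
duration_bands <- function(cuts = c(0, 1, 2, 5, 10, 15, 30)) {
  stopifnot(is.numeric(cuts), length(cuts) >= 1)
  if (cuts[1] != 0) stop("first duration cut must be 0")
  if (any(diff(cuts) <= 0)) stop("duration cuts must be strictly increasing")
  labels <- c(paste0(cuts[-length(cuts)], "-", cuts[-1]),
              paste0(cuts[length(cuts)], "+"))
  structure(list(cuts = cuts, labels = labels), class = "duration_bands")
}

## All duration levels used in tabulated data: general population
## reference, the bands, and "unknown" for prevalent cases without a
## recorded diagnosis date.
duration_levels <- function(bands = duration_bands()) {
  c("pop", bands$labels, "unknown")
}

#' Simulation configuration for the synthetic registry
#'
#' Bundles every tunable of the synthetic-registry generator: cohort
#' size, country study windows, the type 1 diabetes onset-age
#' distribution (strictly below 40 years), the prevalent-case pool,
#' mortality, the population structure and the site-specific baseline
#' rate surfaces.
#'
#' @param n number of cohort members to generate.
#' @param countries character vector of country codes (subset of the
#'   names of `windows`).
#' @param windows named list of `c(start, end)` decimal-year study
#'   windows; defaults to [country_windows()].
#' @param country_weights sampling weights over `countries` (default
#'   equal).
#' @param sexes named numeric of sampling weights, e.g. `c(M=.5,F=.5)`.
#' @param onset_ages integer vector of candidate one-year onset age
#'   bands (all `< 40`).
#' @param onset_weights sampling weights over `onset_ages`; the default
#'   is a childhood-peaked distribution (mode around age 12) with a
#'   long adult tail, mimicking type 1 diabetes onset.
#' @param prevalent_back years before each country's study start from
#'   which diagnosis dates are drawn; diagnoses before study start are
#'   prevalent cases.
#' @param missing_dx_countries countries whose prevalent cases have the
#'   diagnosis date withheld (duration unknown).
#' @param missing_dx_frac fraction of those prevalent cases with the
#'   date withheld.
#' @param mort_rate0,mort_slope Gompertz mortality hazard
#'   `mort_rate0 * exp(mort_slope * age)` (per person-year).
#' @param age_max upper age bound for tabulation and simulation.
#' @param py_per_cell general-population person-years in each one-year
#'   (age, period, sex) cell.
#' @param sites named list of baseline site specifications, each a list
#'   with `rate0` (cases per person-year at `ref_age`, `> 0`),
#'   `ref_age`, `age_slope` (log-linear Gompertz-type age effect) and
#'   `period_drift` (log-linear calendar drift, anchored at 2000).
#' @param min_cases site-eligibility threshold for the duration model
#'   (see [eligible_sites()]).
#' @param seed optional default random seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n = 10000,
                       countries = names(windows),
                       windows = country_windows(),
                       country_weights = NULL,
                       sexes = c(M = 0.5, F = 0.5),
                       onset_ages = 0:39,
                       onset_weights = NULL,
                       prevalent_back = 25,
                       missing_dx_countries = c("AU", "DK"),
                       missing_dx_frac = 1,
                       mort_rate0 = 5e-5,
                       mort_slope = 0.085,
                       age_max = 90,
                       py_per_cell = 1e4,
                       sites = list(all = list(rate0 = 4e-4, ref_age = 25,
                                               age_slope = 0.085,
                                               period_drift = 0.01)),
                       min_cases = 200,
                       seed = NULL) {
  if (is.null(onset_weights)) {
    ## childhood peak near 12 with an adult tail up to 39
    a <- onset_ages
    onset_weights <- stats::dgamma(a + 0.5, shape = 3, scale = 5)
  }
  cfg <- list(n = n, countries = countries, windows = windows,
              country_weights = country_weights %||%
                stats::setNames(rep(1, length(countries)), countries),
              sexes = sexes, onset_ages = onset_ages,
              onset_weights = onset_weights,
              prevalent_back = prevalent_back,
              missing_dx_countries = missing_dx_countries,
              missing_dx_frac = missing_dx_frac,
              mort_rate0 = mort_rate0, mort_slope = mort_slope,
              age_max = age_max, py_per_cell = py_per_cell,
              sites = sites, min_cases = min_cases, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n >= 1, length(cfg$countries) >= 1)
  if (!all(cfg$countries %in% names(cfg$windows)))
    stop("every country needs a study window")
  for (w in cfg$windows[cfg$countries])
    if (length(w) != 2 || w[2] <= w[1]) stop("invalid study window")
  if (any(cfg$onset_ages >= 40))
    stop("type 1 diabetes onset ages must be below 40 years")
  if (length(cfg$onset_ages) != length(cfg$onset_weights) ||
      any(cfg$onset_weights < 0) || sum(cfg$onset_weights) <= 0)
    stop("invalid onset-age weights")
  if (cfg$missing_dx_frac < 0 || cfg$missing_dx_frac > 1)
    stop("missing_dx_frac must be in [0, 1]")
  if (cfg$mort_rate0 < 0) stop("mortality rate must be non-negative")
  if (length(cfg$sites) < 1 || is.null(names(cfg$sites)))
    stop("at least one named site specification is required")
  for (s in cfg$sites) {
    if (is.null(s$rate0) || !is.finite(s$rate0) || s$rate0 <= 0)
      stop("site baseline rate 'rate0' must be a positive number")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic registry configuration\n")
  cat("  persons:  ", x$n, "\n")
  cat("  countries:", paste(x$countries, collapse = ", "), "\n")
  cat("  sites:    ", paste(names(x$sites), collapse = ", "), "\n")
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Flat keys mirror the arguments of [sim_config()]; `windows` and
#' `sites` are nested maps.
#'
#' @param path path to a YAML file.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  ## YAML 1.1 reads a bare key `n` as the boolean "no"; map it back
  names(y)[names(y) == "FALSE"] <- "n"
  if (!is.null(y$windows)) y$windows <- lapply(y$windows, as.numeric)
  if (!is.null(y$sexes)) y$sexes <- unlist(y$sexes)
  do.call(sim_config, y)
}
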