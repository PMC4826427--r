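#' Smooth baseline incidence-rate surface
#'
#' A log-linear ("Gompertz-type") surface over age and calendar time,
#'
#'   log rate(a, p) = intercept + age_slope * a + period_drift * (p - ref_period)
#'
#' in cases per person-year.  It stands in for the smoothly modelled
#' general-population cancer rates that the synthetic registry draws
#' from, and its parameters are recorded so tests can evaluate the
#' truth in closed form.
#'
#' @param intercept log rate at age 0 in the reference period.
#' @param age_slope log-linear age effect per year of age.
#' @param period_drift log-linear calendar drift per calendar year.
#' @param ref_period calendar anchor of the drift term.
#' @param country,sex,site labels carried along for bookkeeping.
#' @return object of class `rate_surface`.
#' @export
rate_surface <- function(intercept, age_slope = 0, period_drift = 0,
                         ref_period = 2000,
                         country = "XX", sex = "M", site = "all") {
  stopifnot(is.finite(intercept), is.finite(age_slope),
            is.finite(period_drift))
  structure(list(intercept = intercept, age_slope = age_slope,
                 period_drift = period_drift, ref_period = ref_period,
                 country = country, sex = sex, site = site),
            class = "rate_surface")
}

#' Build a rate surface from a simulation configuration
#'
#' Looks up the named site's baseline parameters (`rate0` at `ref_age`,
#' `age_slope`, `period_drift`) and returns the corresponding
#' [rate_surface()].  A non-positive baseline rate is rejected.
#'
#' @param config a [sim_config()] object.
#' @param site site name (must exist in `config$sites`).
#' @param sex sex label.
#' @param country country label.
#' @return a `rate_surface`.
#' @export
make_rate_surface <- function(config, site, sex = "M", country = "XX") {
  sp <- config$sites[[site]]
  if (is.null(sp)) stop("unknown site: ", site)
  if (!is.finite(sp$rate0) || sp$rate0 <= 0)
    stop("site baseline rate 'rate0' must be positive")
  rate_surface(intercept = log(sp$rate0) - sp$age_slope * (sp$ref_age %||% 0),
               age_slope = sp$age_slope %||% 0,
               period_drift = sp$period_drift %||% 0,
               ref_period = 2000, country = country, sex = sex, site = site)
}

#' Evaluate the log rate of a surface
#'
#' @param surface a `rate_surface`.
#' @param age age in years (vectorised).
#' @param period calendar time in decimal years (vectorised).
#' @return log cases per person-year.
#' @export
log_rate <- function(surface, age, period) {
  stopifnot(inherits(surface, "rate_surface"))
  surface$intercept + surface$age_slope * age +
    surface$period_drift * (period - surface$ref_period)
}

## Mean rate of a one-year Lexis cell labelled (age, period): the
## surface evaluated at the cell midpoint.  This piecewise-constant
## version of the surface is what both the population table and the
## cohort hazard use, so the simulator is an exact oracle for a model
## evaluated at cell midpoints.
cell_rate <- function(surface, age, period) {
  exp(log_rate(surface, age + 0.5, period + 0.5))
}

#' @export
print.rate_surface <- function(x, ...) {
  cat(sprintf("rate_surface [%s/%s/%s]: log rate = %.4f %+.4f*age %+.4f*(period-%d)\n",
              x$country, x$sex, x$site, x$intercept, x$age_slope,
              x$period_drift, as.integer(x$ref_period)))
  invisible(x)
}
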