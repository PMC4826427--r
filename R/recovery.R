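#' Parameter-recovery and calibration simulation studies
#'
#' Replicated end-to-end studies on the synthetic registry, used to
#' verify that the whole chain (simulation, Lexis splitting,
#' tabulation, model fitting) recovers known ground truth:
#'
#' * `"binary"`: cohorts with a constant true hazard ratio; per
#'   replicate the fitted log hazard ratio, its standard error and
#'   whether the Wald 95% CI covers the truth.
#' * `"duration"`: cohorts with a declining duration profile
#'   (first-band multiplier `profile[1]`, tail 1); per replicate the
#'   fitted first- and last-band contrasts and the Wald z statistic of
#'   their difference.
#' * `"heterogeneity"`: five-country cohorts sharing one true hazard
#'   ratio; per replicate the p value of the between-country
#'   likelihood-ratio test (type-I-error calibration).
#'
#' Study sizes default to one-country male cohorts large enough to
#' yield on the order of 500 cohort cancers (binary) or informative
#' first-band counts (duration); see the package vignette.
#'
#' @param kind study type.
#' @param n_rep number of replicate registries.
#' @param seed base seed; replicate r uses `seed * 1000 + r`.
#' @param true_hr ground-truth hazard ratio (binary / heterogeneity).
#' @param profile duration-band multipliers (duration study).
#' @param n cohort size per replicate (defaults by study kind).
#' @param countries countries simulated (defaults by study kind).
#' @param n_knots interior knots per timescale in the fitted models.
#' @return data.frame with one row per replicate; columns depend on
#'   `kind` (see above), always including `events` (cohort cancers).
#' @export
recovery_study <- function(kind = c("binary", "duration", "heterogeneity"),
                           n_rep = 20, seed = 1, true_hr = 1.5,
                           profile = c(2.3, 1.2, 1.1, 1.05, 1, 1, 1),
                           n = NULL, countries = NULL, n_knots = 5) {
  kind <- match.arg(kind)
  n <- n %||% switch(kind, binary = 5000, duration = 100000,
                     heterogeneity = 30000)
  countries <- countries %||%
    switch(kind, binary = "FI", duration = "FI",
           heterogeneity = c("AU", "DK", "FI", "SC", "SE"))
  bands <- duration_bands()
  eff <- switch(kind,
                binary = ,
                heterogeneity = list(all = true_effect("all",
                                                       binary = true_hr)),
                duration = list(all = true_effect(
                  "all", duration = stats::setNames(profile, bands$labels))))
  cfg <- sim_config(n = n, countries = countries, sexes = c(M = 1))

  one <- function(r) {
    ## replicate seeds stay well below .Machine$integer.max
    reg <- simulate_registry(cfg, eff, seed = (seed %% 2146483) * 1000 + r)
    seg <- split_follow_up(reg$cohort, variant = "all_sites",
                           windows = cfg$windows, age_max = cfg$age_max)
    cells <- tabulate_lexis(seg)
    rt <- rate_table(cells, reg$population, site = "all",
                     age_max = cfg$age_max)
    events <- sum(rt$events[rt$duration != "pop"])
    if (kind == "binary") {
      fit <- suppressWarnings(apcfit(rt, diabetes = "binary",
                                     n_knots = n_knots))
      b <- fit$coefficients["t1d"]
      se <- sqrt(fit$vcov["t1d", "t1d"])
      data.frame(rep = r, events = events, delta = unname(b),
                 se = unname(se),
                 covered = abs(b - log(true_hr)) <= 1.96 * se)
    } else if (kind == "duration") {
      fit <- suppressWarnings(apcfit(rt, diabetes = "duration",
                                     n_knots = n_knots))
      l1 <- paste0("dur", bands$labels[1])
      l7 <- paste0("dur", bands$labels[length(bands$labels)])
      d <- fit$coefficients[l1] - fit$coefficients[l7]
      sed <- sqrt(fit$vcov[l1, l1] + fit$vcov[l7, l7] -
                    2 * fit$vcov[l1, l7])
      data.frame(rep = r, events = events,
                 delta_first = unname(fit$coefficients[l1]),
                 delta_last = unname(fit$coefficients[l7]),
                 z_diff = unname(d / sed))
    } else {
      h <- suppressWarnings(heterogeneity_test(rt, n_knots = n_knots))
      data.frame(rep = r, events = events, p = h$p.value)
    }
  }
  out <- do.call(rbind, lapply(seq_len(n_rep), one))
  attr(out, "kind") <- kind
  attr(out, "true_hr") <- true_hr
  out
}
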