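#' Hazard-ratio table from a fitted model
#'
#' Exponentiates the delta coefficients and their Wald 95% confidence
#' limits (`exp(delta +- 1.96 SE)` on the log scale), one row per delta
#' level in band order.  Levels on the likelihood boundary (zero
#' events) are returned as `NA`.
#'
#' @param fit a converged [apcfit()] object.
#' @param z normal quantile for the confidence limits (1.96 for 95%).
#' @return data.frame: level, hr, lo95, hi95, se_log.
#' @export
hr_table <- function(fit, z = 1.96) {
  stopifnot(inherits(fit, "apcfit"))
  if (!fit$converged)
    stop("refusing to tabulate hazard ratios from a non-converged fit")
  idx <- fit$design$delta_idx
  lab <- fit$design$delta_labels
  b <- fit$coefficients[idx]
  se <- sqrt(diag(fit$vcov)[idx])
  bad <- is.na(b) | fit$boundary
  b[bad] <- NA; se[bad] <- NA
  data.frame(level = lab, hr = exp(b), lo95 = exp(b - z * se),
             hi95 = exp(b + z * se), se_log = se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Likelihood-ratio test for between-country heterogeneity of the
#' type 1 diabetes hazard ratio
#'
#' Fits the model with a single common delta and the extended model
#' with one delta per country, and compares them by a likelihood-ratio
#' chi-square on `countries - 1` degrees of freedom.
#'
#' @param data Lexis-cell table (see [apcfit()]), binary model.
#' @param ... further arguments passed to [apcfit()].
#' @return an object of class `htest`.
#' @export
heterogeneity_test <- function(data, ...) {
  cn <- unique(data$country[data$duration != "pop" & data$events > 0])
  if (length(unique(data$country)) < 2 || length(cn) < 2)
    stop("heterogeneity test needs at least two countries with ",
         "type 1 diabetes events")
  fit0 <- apcfit(data, diabetes = "binary", per_country = FALSE, ...)
  fit1 <- apcfit(data, diabetes = "binary", per_country = TRUE, ...)
  lr <- max(0, fit0$deviance - fit1$deviance)
  df <- length(unique(data$country)) - 1
  structure(list(statistic = c(`LR chi-square` = lr),
                 parameter = c(df = df),
                 p.value = stats::pchisq(lr, df, lower.tail = FALSE),
                 method = paste("Likelihood-ratio test of a common vs",
                                "per-country type 1 diabetes hazard ratio"),
                 data.name = deparse(substitute(data))),
            class = "htest")
}

#' Likelihood-ratio test of an age-at-diagnosis interaction
#'
#' Tests whether the type 1 diabetes hazard ratio differs by age at
#' diabetes diagnosis (bands `<30`, `30-35`, `35-40`), probing the
#' under-40 cohort definition: the common-delta binary model is
#' compared with the model in which delta varies by diagnosis-age
#' band, on 2 degrees of freedom.  Cohort rows without a known band
#' are excluded from both fits; an empty band is refused by name.
#'
#' @param data Lexis-cell table including a `dx_band` column
#'   (tabulate with `by_dx_band = TRUE`).
#' @param ... further arguments passed to [apcfit()].
#' @return an object of class `htest` with the per-band estimates
#'   attached as attribute `"hr"`.
#' @export
age_at_dx_interaction <- function(data, ...) {
  if (!"dx_band" %in% names(data))
    stop("data needs a dx_band column (tabulate with by_dx_band = TRUE)")
  drop <- data$duration != "pop" &
    (is.na(data$dx_band) | data$dx_band == "unknown")
  d <- data[!drop, , drop = FALSE]
  fit0 <- apcfit(d, diabetes = "binary", dx_age = FALSE, ...)
  fit1 <- apcfit(d, diabetes = "binary", dx_age = TRUE, ...)
  lr <- max(0, fit0$deviance - fit1$deviance)
  out <- structure(list(statistic = c(`LR chi-square` = lr),
                        parameter = c(df = 2),
                        p.value = stats::pchisq(lr, 2, lower.tail = FALSE),
                        method = paste("Likelihood-ratio test of an age-at-",
                                       "diagnosis interaction with the type 1",
                                       " diabetes hazard ratio"),
                        data.name = deparse(substitute(data))),
                   class = "htest")
  attr(out, "hr") <- hr_table(fit1)
  out
}

#' Site eligibility for the duration model
#'
#' A site enters the duration analysis when there are at least
#' `min_cases` cohort cancer cases for each sex in which the site
#' occurs (sex-specific sites are judged on their single sex), or when
#' the site is in the override list (kidney by default, because of its
#' established association with type 2 diabetes).
#'
#' @param counts data.frame with columns site, sex, cases (cohort case
#'   counts).
#' @param min_cases threshold (default 200).
#' @param override sites always eligible.
#' @return named logical vector over the sites in `counts`.
#' @export
eligible_sites <- function(counts, min_cases = 200, override = "kidney") {
  stopifnot(all(c("site", "sex", "cases") %in% names(counts)),
            all(counts$cases >= 0))
  sites <- unique(counts$site)
  out <- vapply(sites, function(s) {
    if (s %in% override) return(TRUE)
    cs <- counts$cases[counts$site == s]
    length(cs) >= 1 && all(cs >= min_cases)
  }, TRUE)
  names(out) <- sites
  out
}

#' Classical standardised incidence ratio
#'
#' Observed cohort events divided by the events expected under the
#' empirical general-population rates, summed over the shared
#' (country, sex, age, period) strata.  The smooth model's binary
#' hazard ratio rests on the same proportional-hazards assumption, so
#' this classical ratio serves as an independent oracle: on a single
#' stratum the two coincide exactly.
#'
#' @param data Lexis-cell table with population rows (`duration ==
#'   "pop"`) and cohort rows.
#' @return the ratio observed/expected (a single number).
#' @export
smr <- function(data) {
  strat <- function(d) paste(d$country, d$sex %||% "", d$age, d$period,
                             sep = "\r")
  pop <- data[data$duration == "pop", , drop = FALSE]
  t1d <- data[data$duration != "pop", , drop = FALSE]
  if (nrow(t1d) == 0 || nrow(pop) == 0)
    stop("need both cohort and population cells")
  pr <- rowsum(cbind(pop$events, pop$pyrs), strat(pop))
  rate <- stats::setNames(pr[, 1] / pr[, 2], rownames(pr))
  key <- strat(t1d)
  if (any(!key %in% names(rate)))
    stop("cohort strata missing from the population table")
  expected <- sum(t1d$pyrs * rate[key])
  if (expected <= 0) stop("zero expected count")
  sum(t1d$events) / expected
}
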