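## ---- internal time-grid machinery -----------------------------------------
##
## Partition each person's interval [entry_i, exit_i) at every integer
## age boundary (anchored at date of birth), every integer calendar
## year, every duration cut (anchored at the diagnosis date) and any
## extra absolute cut times.  Within the resulting segments every
## piecewise-constant hazard used in this package is exactly constant,
## which makes the simulator an exact oracle for the rate model.
##
## Returns data.frame(i, t0, t1) ordered by (i, t0); persons with
## entry == exit contribute no rows.
.time_grid <- function(entry, exit, dob = NULL, dx = NULL,
                       dur_cuts = NULL, period = TRUE, extra = NULL) {
  np <- length(entry)
  eps <- 1e-9
  ids <- list(i0 = seq_len(np), i1 = seq_len(np))
  ts <- list(t0 = entry, t1 = exit)

  add_integer_cuts <- function(anchor) {
    k_lo <- floor(entry - anchor + eps) + 1
    k_hi <- ceiling(exit - anchor - eps) - 1
    nn <- as.integer(pmax(0, k_hi - k_lo + 1))
    nn[is.na(nn)] <- 0L
    list(i = rep(seq_len(np), nn),
         t = rep(anchor, nn)[seq_len(sum(nn))] +
           (sequence(nn) - 1L) + rep(k_lo, nn))
  }
  if (!is.null(dob)) {
    z <- add_integer_cuts(dob); ids$age <- z$i; ts$age <- z$t
  }
  if (isTRUE(period)) {
    z <- add_integer_cuts(rep(0, np)); ids$per <- z$i; ts$per <- z$t
  }
  if (!is.null(dx) && !is.null(dur_cuts)) {
    for (ct in dur_cuts) {
      t <- dx + ct
      keep <- !is.na(t) & t > entry + eps & t < exit - eps
      ids[[paste0("d", ct)]] <- which(keep)
      ts[[paste0("d", ct)]] <- t[keep]
    }
  }
  if (!is.null(extra)) {
    for (et in extra) {
      keep <- et > entry + eps & et < exit - eps
      ids[[paste0("x", et)]] <- which(keep)
      ts[[paste0("x", et)]] <- rep(et, sum(keep))
    }
  }

  i_all <- unlist(ids, use.names = FALSE)
  t_all <- unlist(ts, use.names = FALSE)
  o <- order(i_all, t_all)
  i_all <- i_all[o]; t_all <- t_all[o]
  dup <- c(FALSE, diff(i_all) == 0 & diff(t_all) < eps)
  i_all <- i_all[!dup]; t_all <- t_all[!dup]
  m <- length(i_all)
  if (m < 2)
    return(data.frame(i = integer(0), t0 = numeric(0), t1 = numeric(0)))
  keep <- which(i_all[-m] == i_all[-1])
  data.frame(i = i_all[keep], t0 = t_all[keep], t1 = t_all[keep + 1])
}

## Draw one event time per person from a piecewise-constant hazard on a
## time grid, by inverse-CDF on the piecewise-exponential segments.
## grid: data.frame(i, t0, t1) ordered by (i, t0); hazard: per grid row.
## Returns numeric(n_persons): event time or NA (no event in the grid).
.pw_exp_draw <- function(grid, hazard, n_persons) {
  out <- rep(NA_real_, n_persons)
  if (nrow(grid) == 0) return(out)
  e_target <- stats::rexp(n_persons)
  H <- hazard * (grid$t1 - grid$t0)
  cumH <- cumsum(H)
  firsts <- which(!duplicated(grid$i))
  grp <- cumsum(!duplicated(grid$i))
  before <- (cumH - H) - (cumH[firsts] - H[firsts])[grp]
  within <- before + H
  e_row <- e_target[grid$i]
  hit <- within >= e_row & before < e_row
  idx <- which(hit)
  out[grid$i[idx]] <- grid$t0[idx] + (e_row[idx] - before[idx]) / hazard[idx]
  out
}

## ---- ground-truth effects --------------------------------------------------

#' Ground-truth hazard-ratio specification for one site
#'
#' The synthetic cohort's cancer hazard is the population rate times a
#' duration-dependent multiplier.  `duration` gives one positive rate
#' ratio per duration band; if omitted, the single `binary` ratio is
#' used in every band (the simple type 1 diabetes vs population
#' contrast).  The default duration profile follows the qualitative
#' shape reported for all cancers: a high first-year ratio (surveillance
#' ascertainment) declining towards 1.
#'
#' @param site site name.
#' @param duration named numeric of rate ratios, names matching the
#'   band labels of `bands`; or `NULL` to use `binary` throughout.
#' @param binary single rate ratio for the simple model.
#' @param sex label (informational; default applies to both sexes).
#' @param bands a [duration_bands()] object.
#' @return object of class `true_effect`.
#' @export
true_effect <- function(site = "all", duration = NULL, binary = 1,
                        sex = "both", bands = duration_bands()) {
  if (!is.null(duration)) {
    if (!setequal(names(duration), bands$labels))
      stop("duration multipliers must be named by the band labels: ",
           paste(bands$labels, collapse = ", "))
    duration <- duration[bands$labels]
    if (any(!is.finite(duration) | duration <= 0))
      stop("all duration multipliers must be positive")
  }
  if (!is.finite(binary) || binary <= 0)
    stop("binary multiplier must be positive")
  structure(list(site = site, duration = duration, binary = binary,
                 sex = sex, bands = bands), class = "true_effect")
}

#' Default ground-truth duration profile
#'
#' First-year multiplier 2.3 declining to 1 over the duration bands.
#'
#' @param site site name.
#' @return a [true_effect()] object.
#' @export
default_true_effect <- function(site = "all") {
  b <- duration_bands()
  true_effect(site,
              duration = stats::setNames(
                c(2.3, 1.2, 1.1, 1.05, 1, 1, 1), b$labels),
              bands = b)
}

## Per-band multiplier vector (length = number of bands) for an effect.
.effect_multipliers <- function(effect) {
  nb <- length(effect$bands$labels)
  if (is.null(effect$duration)) rep(effect$binary, nb)
  else unname(effect$duration)
}

## ---- population table ------------------------------------------------------

#' Default general-population structure
#'
#' Person-years per one-year (country, sex, age, period) cell, constant
#' at `config$py_per_cell` over ages `0:(age_max-1)` and each country's
#' study window.  Realistic national demography is deliberately out of
#' scope; the structure only has to carry the offsets.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns country, sex, age, period,
#'   person_years.
#' @export
pop_structure <- function(config) {
  out <- lapply(config$countries, function(cn) {
    w <- config$windows[[cn]]
    periods <- seq(floor(w[1]), ceiling(w[2]) - 1)
    g <- expand.grid(sex = names(config$sexes),
                     age = 0:(config$age_max - 1), period = periods,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$country <- cn
    g$person_years <- config$py_per_cell
    g[, c("country", "sex", "age", "period", "person_years")]
  })
  do.call(rbind, out)
}

#' Simulate a general-population rate table
#'
#' Case counts are drawn as Poisson with mean `person_years` times the
#' mean cell rate of the site's surface; person-years are copied
#' through unchanged.  The table represents the total background
#' population (which includes the type 1 diabetes members; at a
#' prevalence below 1% the contamination of the baseline is ignored).
#'
#' @param surfaces a single [rate_surface()] or a named list of them
#'   (one per site).
#' @param structure data.frame with columns country, sex, age, period,
#'   person_years (see [pop_structure()]).
#' @param seed optional seed set before drawing.
#' @return data.frame: country, sex, age, period, site, person_years,
#'   cases.
#' @export
simulate_population_table <- function(surfaces, structure, seed = NULL) {
  if (inherits(surfaces, "rate_surface"))
    surfaces <- stats::setNames(list(surfaces), surfaces$site)
  if (any(structure$person_years < 0))
    stop("person-years must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(surfaces), function(s) {
    mu <- structure$person_years *
      cell_rate(surfaces[[s]], structure$age, structure$period)
    data.frame(structure[, c("country", "sex", "age", "period")],
               site = s, person_years = structure$person_years,
               cases = stats::rpois(nrow(structure), mu))
  })
  do.call(rbind, out)
}

## ---- cohort simulation -----------------------------------------------------

#' Simulate a person-level type 1 diabetes cohort
#'
#' Each person receives a country, sex, onset age (below 40), a
#' diagnosis date drawn between `prevalent_back` years before the
#' country's study start and its end, and a birth date implied by the
#' two.  Entry is the later of study start and diagnosis.  A first
#' primary cancer time is then drawn from the piecewise-constant hazard
#' (population cell rate x duration-band multiplier) by inverse-CDF on
#' the piecewise-exponential segments cut at every age-year,
#' calendar-year and duration-band boundary; death comes independently
#' from the Gompertz mortality hazard.  Exit is the earliest of cancer,
#' death and study end.  Prevalent cases in `missing_dx_countries`
#' have the diagnosis date withheld with probability `missing_dx_frac`
#' (duration then unknown downstream).
#'
#' @param config a [sim_config()] object.
#' @param effects named list of [true_effect()] objects covering every
#'   configured site.
#' @param seed integer seed (required; defaults to `config$seed`).
#' @return data.frame, one row per person: id, country, sex, dob, dx,
#'   cancer_time, cancer_site, death_time, entry, exit (all times in
#'   decimal years; dx is `NA` where withheld).
#' @export
simulate_t1d_cohort <- function(config, effects, seed = config$seed) {
  if (is.null(seed)) stop("a seed is required for cohort simulation")
  if (length(effects) == 0) stop("at least one true_effect is required")
  if (is.null(names(effects)))
    names(effects) <- vapply(effects, function(e) e$site, "")
  missing_eff <- setdiff(names(config$sites), names(effects))
  if (length(missing_eff))
    stop("effects must cover all configured sites; missing: ",
         paste(missing_eff, collapse = ", "))
  unknown <- setdiff(names(effects), names(config$sites))
  if (length(unknown))
    stop("unknown site: ", paste(unknown, collapse = ", "))
  set.seed(seed)
  n <- config$n
  cn <- sample(config$countries, n, replace = TRUE,
               prob = config$country_weights[config$countries])
  sex <- sample(names(config$sexes), n, replace = TRUE, prob = config$sexes)
  onset <- sample(config$onset_ages, n, replace = TRUE,
                  prob = config$onset_weights) + stats::runif(n)
  w0 <- vapply(config$windows[cn], `[`, 0, 1)
  w1 <- vapply(config$windows[cn], `[`, 0, 2)
  dx <- w0 - config$prevalent_back +
    stats::runif(n) * (w1 - (w0 - config$prevalent_back))
  dob <- dx - onset
  entry <- pmax(w0, dx)
  w_end <- pmin(w1, dob + config$age_max)
  keep <- entry < w_end
  ## (persons ageing out before entry are not cohort members)
  n <- sum(keep)
  cn <- cn[keep]; sex <- sex[keep]; dx <- dx[keep]; dob <- dob[keep]
  entry <- entry[keep]; w0 <- w0[keep]; w1 <- w1[keep]; w_end <- w_end[keep]

  eps <- 1e-9
  ## death first, on the age-cut grid (mortality depends on age only)
  g_d <- .time_grid(entry, w_end, dob = dob, period = FALSE)
  age_lab <- floor(g_d$t0 - dob[g_d$i] + eps)
  h_d <- config$mort_rate0 * exp(config$mort_slope * (age_lab + 0.5))
  death <- .pw_exp_draw(g_d, h_d, n)

  ## cancer, at risk from entry until death or study end
  risk_end <- pmin(ifelse(is.na(death), Inf, death), w_end)
  bands <- duration_bands()
  g <- .time_grid(entry, risk_end, dob = dob, dx = dx,
                  dur_cuts = bands$cuts[-1], period = TRUE)
  a_lab <- floor(g$t0 - dob[g$i] + eps)
  p_lab <- floor(g$t0 + eps)
  b_idx <- findInterval(g$t0 - dx[g$i] + eps, bands$cuts)
  sites <- names(config$sites)
  h_site <- matrix(0, nrow(g), length(sites),
                   dimnames = list(NULL, sites))
  for (s in sites) {
    surf <- make_rate_surface(config, s)
    mult <- .effect_multipliers(effects[[s]])
    h_site[, s] <- cell_rate(surf, a_lab, p_lab) * mult[b_idx]
  }
  h_tot <- rowSums(h_site)
  cancer <- .pw_exp_draw(g, h_tot, n)

  cancer_site <- rep(NA_character_, n)
  ev <- which(!is.na(cancer))
  if (length(ev)) {
    ## locate the event segment of each event person to pick the site
    seg_of <- rep(NA_integer_, n)
    inseg <- which(cancer[g$i] >= g$t0 - eps & cancer[g$i] < g$t1 + eps)
    seg_of[g$i[inseg]] <- inseg  # last matching segment wins; unique in practice
    for (p in ev) {
      w <- h_site[seg_of[p], ]
      cancer_site[p] <- if (length(sites) == 1) sites else
        sample(sites, 1, prob = w)
    }
  }

  exit <- pmin(ifelse(is.na(cancer), Inf, cancer), risk_end)
  death_obs <- ifelse(!is.na(death) & death < w_end, death, NA_real_)

  ## withhold diagnosis dates for prevalent cases where configured
  dx_obs <- dx
  prev <- dx < w0 & cn %in% config$missing_dx_countries
  hide <- prev & stats::runif(n) < config$missing_dx_frac
  dx_obs[hide] <- NA_real_

  data.frame(id = seq_len(n), country = cn, sex = sex, dob = dob,
             dx = dx_obs, cancer_time = cancer, cancer_site = cancer_site,
             death_time = death_obs, entry = entry, exit = exit,
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic registry (cohort plus population table)
#'
#' @inheritParams simulate_t1d_cohort
#' @return list with elements `cohort` (see [simulate_t1d_cohort()])
#'   and `population` (see [simulate_population_table()]).
#' @export
simulate_registry <- function(config, effects, seed = config$seed) {
  cohort <- simulate_t1d_cohort(config, effects, seed = seed)
  surfaces <- stats::setNames(
    lapply(names(config$sites), function(s) make_rate_surface(config, s)),
    names(config$sites))
  population <- simulate_population_table(surfaces, pop_structure(config))
  list(cohort = cohort, population = population)
}

#' Write the person-level cohort as CSV
#'
#' Emits both ISO-8601 date columns and the decimal-year columns.
#'
#' @param cohort data.frame from [simulate_t1d_cohort()].
#' @param path output file.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(id = cohort$id, country = cohort$country,
                    sex = cohort$sex,
                    dob = as_cal_date(cohort$dob),
                    dx_date = as_cal_date(cohort$dx),
                    cancer_date = as_cal_date(cohort$cancer_time),
                    cancer_site = cohort$cancer_site,
                    death_date = as_cal_date(cohort$death_time),
                    entry = as_cal_date(cohort$entry),
                    exit = as_cal_date(cohort$exit),
                    dob_dec = cohort$dob, dx_dec = cohort$dx,
                    cancer_dec = cohort$cancer_time,
                    death_dec = cohort$death_time,
                    entry_dec = cohort$entry, exit_dec = cohort$exit)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a person-level cohort CSV written by [write_cohort_csv()]
#'
#' Decimal-year columns are used when present; otherwise dates are
#' converted with [decimal_year()] (month-precision dates should be
#' imputed to day 15 upstream).
#'
#' @param path input file.
#' @return cohort data.frame in the internal decimal-year schema.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  getcol <- function(dec, date) {
    if (dec %in% names(d)) as.numeric(d[[dec]])
    else decimal_year(as.Date(d[[date]]))
  }
  data.frame(id = d$id, country = d$country, sex = d$sex,
             dob = getcol("dob_dec", "dob"),
             dx = getcol("dx_dec", "dx_date"),
             cancer_time = getcol("cancer_dec", "cancer_date"),
             cancer_site = ifelse(d$cancer_site == "" | is.na(d$cancer_site),
                                  NA_character_, d$cancer_site),
             death_time = getcol("death_dec", "death_date"),
             entry = getcol("entry_dec", "entry"),
             exit = getcol("exit_dec", "exit"),
             stringsAsFactors = FALSE)
}
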