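#' Split follow-up along the age, period and duration timescales
#'
#' Partitions each person's follow-up `[entry, exit)` at every age-year
#' birthday, calendar-year boundary and diabetes-duration cut point.
#' All intervals are half-open `[t0, t1)`; an event falling exactly on
#' a boundary belongs to the segment starting there, except the
#' terminating event at `exit` which belongs to the last segment.
#' Person-time is conserved exactly: the segment lengths of a person
#' sum to `exit - entry`.
#'
#' Two censoring variants are supported.  Under `"all_sites"` follow-up
#' ends at the first cancer, death or study end, whichever comes first
#' (the convention for all cancers combined and the non-sex-specific
#' grouping).  Under `"site_specific"` follow-up runs to death or study
#' end, ignoring the cancer date, so that one set of person-years
#' serves every site-specific analysis; this overestimates cohort
#' person-time slightly (see [overestimation_check()]).
#'
#' @param cohort person table as returned by [simulate_t1d_cohort()] or
#'   [read_cohort_csv()]: columns id, country, sex, dob, dx (NA allowed),
#'   cancer_time, cancer_site, death_time, entry (all decimal years).
#' @param bands a [duration_bands()] object.
#' @param variant censoring variant, see above.
#' @param windows named list of country study windows.
#' @param age_max follow-up is truncated at this age (default 90).
#' @param extra_cuts optional extra absolute decimal-year cut times
#'   applied to every person (refining the break set never changes any
#'   aggregate).
#' @return data.frame of follow-up segments: id, country, sex, age,
#'   period, cohort (= period - age), duration (band label, `"pop"`
#'   never occurs here, `"unknown"` when the diagnosis date is
#'   withheld), dx_band (age-at-diagnosis band, NA when unknown),
#'   pyrs, event (0/1), site (event site or NA), variant.
#' @export
split_follow_up <- function(cohort, bands = duration_bands(),
                            variant = c("all_sites", "site_specific"),
                            windows = country_windows(), age_max = 90,
                            extra_cuts = NULL) {
  variant <- match.arg(variant)
  eps <- 1e-9
  if (nrow(cohort) == 0) stop("empty cohort")
  if (!all(cohort$country %in% names(windows)))
    stop("missing study window for country: ",
         paste(setdiff(unique(cohort$country), names(windows)),
               collapse = ", "))
  w1 <- vapply(windows[cohort$country], `[`, 0, 2)
  inf_na <- function(x) ifelse(is.na(x), Inf, x)
  cap <- pmin(w1, cohort$dob + age_max)
  exit_v <- if (variant == "all_sites")
    pmin(inf_na(cohort$cancer_time), inf_na(cohort$death_time), cap)
  else
    pmin(inf_na(cohort$death_time), cap)
  entry <- cohort$entry
  if (any(exit_v < entry - eps))
    stop("exit precedes entry for some persons")
  if (any(!is.na(cohort$dx) & cohort$dx > entry + eps))
    stop("entry precedes diabetes diagnosis for some persons")

  g <- .time_grid(entry, exit_v, dob = cohort$dob, dx = cohort$dx,
                  dur_cuts = bands$cuts[-1], period = TRUE,
                  extra = extra_cuts)
  if (nrow(g) == 0)
    return(empty_segments())
  i <- g$i
  age <- floor(g$t0 - cohort$dob[i] + eps)
  period <- floor(g$t0 + eps)
  dxi <- cohort$dx[i]
  dur <- rep("unknown", length(i))
  known <- !is.na(dxi)
  dur[known] <- bands$labels[findInterval(g$t0[known] - dxi[known] + eps,
                                          bands$cuts)]
  dx_age <- cohort$dx - cohort$dob
  dx_band <- cut(dx_age, c(0, 30, 35, 40), right = FALSE,
                 labels = c("<30", "30-35", "35-40"),
                 include.lowest = TRUE)

  ## attach events: strictly interior events to their half-open
  ## segment, the terminating event (at exit) to the last segment
  ev_time <- cohort$cancer_time
  ev_time[ev_time > exit_v + eps] <- NA  # beyond this variant's follow-up
  event <- !is.na(ev_time[i]) &
    ev_time[i] >= g$t0 - eps & ev_time[i] < g$t1 - eps
  at_exit <- which(!is.na(ev_time) & ev_time >= exit_v - eps)
  if (length(at_exit)) {
    last_row <- length(i) - match(at_exit, rev(i)) + 1
    event[last_row[!is.na(last_row)]] <- TRUE
  }
  site <- rep(NA_character_, length(i))
  site[event] <- if (variant == "all_sites") "all" else
    cohort$cancer_site[i[event]]

  out <- data.frame(id = cohort$id[i], country = cohort$country[i],
                    sex = cohort$sex[i], age = age, period = period,
                    cohort = period - age, duration = dur,
                    dx_band = as.character(dx_band)[i],
                    pyrs = g$t1 - g$t0,
                    event = as.integer(event), site = site,
                    variant = variant, stringsAsFactors = FALSE)
  out[out$pyrs > 0, , drop = FALSE]
}

empty_segments <- function() {
  data.frame(id = integer(0), country = character(0), sex = character(0),
             age = integer(0), period = integer(0), cohort = integer(0),
             duration = character(0), dx_band = character(0),
             pyrs = numeric(0), event = integer(0), site = character(0),
             variant = character(0), stringsAsFactors = FALSE)
}

#' Aggregate follow-up segments into an events/person-years table
#'
#' Sums events and person-years per stratum (country, sex, one-year
#' age, one-year period, duration level and optionally age-at-diagnosis
#' band); cohort is computed as period - age on the cell labels.  For
#' each requested site one row per stratum carries that site's event
#' count together with the stratum person-years (person-time is shared
#' across sites under the `"site_specific"` variant).
#'
#' @param segments output of [split_follow_up()] (a single variant).
#' @param sites sites to tabulate; defaults to the event sites present.
#' @param by_dx_band include the age-at-diagnosis band in the stratum
#'   key (rows with unknown band keep `NA`).
#' @return data.frame of Lexis cells: country, sex, age, period,
#'   cohort, duration, (dx_band,) site, events, pyrs.  Total events and
#'   person-years are conserved.
#' @export
tabulate_lexis <- function(segments, sites = NULL, by_dx_band = FALSE) {
  if (length(unique(segments$variant)) > 1)
    stop("segments from mixed censoring variants cannot be tabulated together")
  if (nrow(segments) == 0) stop("no segments to tabulate")
  if (is.null(sites)) {
    sites <- sort(unique(segments$site[!is.na(segments$site)]))
    if (length(sites) == 0) sites <- "all"
  }
  keycols <- c("country", "sex", "age", "period", "duration",
               if (by_dx_band) "dx_band")
  keydat <- segments[keycols]
  if (by_dx_band) keydat$dx_band[is.na(keydat$dx_band)] <- "unknown"
  ## mixed-radix integer key (much faster than pasting strings);
  ## the code product stays far below 2^53 so the double is exact
  key <- 0
  for (col in keydat) {
    u <- unique(col)
    key <- key * length(u) + (match(col, u) - 1)
  }
  uk <- !duplicated(key)
  pyrs <- rowsum(segments$pyrs, key, reorder = FALSE)
  out <- lapply(sites, function(s) {
    ev <- rowsum(as.numeric(segments$event == 1L &
                              !is.na(segments$site) &
                              segments$site == s),
                 key, reorder = FALSE)
    cbind(keydat[uk, , drop = FALSE],
          data.frame(site = s, events = as.vector(ev),
                     pyrs = as.vector(pyrs), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  out$cohort <- out$period - out$age
  rownames(out) <- NULL
  ord <- c("country", "sex", "age", "period", "cohort", "duration",
           if (by_dx_band) "dx_band", "site", "events", "pyrs")
  out[out$pyrs > 0, ord, drop = FALSE]
}

#' Person-time overestimation of the site-specific censoring variant
#'
#' Measuring follow-up to death or study end (ignoring the cancer date)
#' overestimates cohort person-time relative to censoring at the first
#' cancer.  Returns the relative excess
#' `(Y_site_specific - Y_all_sites) / Y_all_sites`.
#'
#' @inheritParams split_follow_up
#' @return a single number (0 when no cancers occur).
#' @export
overestimation_check <- function(cohort, windows = country_windows(),
                                 age_max = 90) {
  if (nrow(cohort) == 0) stop("empty cohort")
  w1 <- vapply(windows[cohort$country], `[`, 0, 2)
  inf_na <- function(x) ifelse(is.na(x), Inf, x)
  cap <- pmin(w1, cohort$dob + age_max)
  y_as <- sum(pmin(inf_na(cohort$cancer_time), inf_na(cohort$death_time),
                   cap) - cohort$entry)
  y_ss <- sum(pmin(inf_na(cohort$death_time), cap) - cohort$entry)
  (y_ss - y_as) / y_as
}

#' Combine cohort cells with the population table into a model table
#'
#' Stacks the type 1 diabetes Lexis cells for one site on top of the
#' general-population rows (duration level `"pop"`), the input expected
#' by [apcfit()].
#'
#' @param cells output of [tabulate_lexis()].
#' @param population table from [simulate_population_table()] (columns
#'   country, sex, age, period, site, person_years, cases).
#' @param site site to model.
#' @param sex optional sex to restrict to.
#' @param age_max drop cells at or above this age.
#' @return data.frame with columns country, sex, age, period, cohort,
#'   duration, (dx_band,) events, pyrs.
#' @export
rate_table <- function(cells, population, site = "all", sex = NULL,
                       age_max = 90) {
  t1d <- cells[cells$site == site, , drop = FALSE]
  pop <- population[population$site == site, , drop = FALSE]
  if (nrow(t1d) == 0 && nrow(pop) == 0) stop("unknown site: ", site)
  hasdx <- "dx_band" %in% names(t1d)
  pop <- data.frame(country = pop$country, sex = pop$sex, age = pop$age,
                    period = pop$period, cohort = pop$period - pop$age,
                    duration = "pop", events = pop$cases,
                    pyrs = pop$person_years, stringsAsFactors = FALSE)
  if (hasdx) pop$dx_band <- NA_character_
  cols <- c("country", "sex", "age", "period", "cohort", "duration",
            if (hasdx) "dx_band", "events", "pyrs")
  out <- rbind(t1d[, cols, drop = FALSE], pop[, cols, drop = FALSE])
  if (!is.null(sex)) out <- out[out$sex %in% sex, , drop = FALSE]
  out <- out[out$age < age_max & out$pyrs > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
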