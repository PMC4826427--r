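## Small shared fixtures for fast tests.

## A flat, single-country, single-sex configuration whose cancer rate
## is constant over age and period, so closed-form expectations are
## available everywhere.
flat_config <- function(n = 4000, rate0 = 2e-3, mort_rate0 = 0,
                        countries = "DK") {
  sim_config(n = n, countries = countries, sexes = c(M = 1),
             mort_rate0 = mort_rate0,
             missing_dx_countries = character(0),
             sites = list(all = list(rate0 = rate0, ref_age = 25,
                                     age_slope = 0, period_drift = 0)))
}

## Simulated registry + all-sites rate table for a config (one site).
small_rate_table <- function(cfg, effects, seed) {
  reg <- simulate_registry(cfg, effects, seed = seed)
  seg <- split_follow_up(reg$cohort, windows = cfg$windows,
                         age_max = cfg$age_max)
  rate_table(tabulate_lexis(seg), reg$population, site = "all",
             age_max = cfg$age_max)
}

## Hand-built two-stratum rate table (one cohort and one population
## cell per stratum) for algebraic oracle checks.
two_cell_table <- function(ev_t1d, py_t1d, ev_pop, py_pop,
                           age = 30, period = 2000) {
  data.frame(country = "DK", sex = "M",
             age = age, period = period, cohort = period - age,
             duration = c("5-10", "pop"),
             events = c(ev_t1d, ev_pop), pyrs = c(py_t1d, py_pop),
             stringsAsFactors = FALSE)
}
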