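test_that("site eligibility requires the threshold in every sex, with overrides", {
  counts <- data.frame(
    site = c("colon", "colon", "prostate", "kidney", "kidney", "thyroid",
             "thyroid"),
    sex = c("M", "F", "M", "M", "F", "M", "F"),
    cases = c(250, 300, 553, 60, 45, 199, 500))
  e <- eligible_sites(counts)
  expect_true(e[["colon"]])       # both sexes >= 200
  expect_true(e[["prostate"]])    # sex-specific site judged on one sex
  expect_true(e[["kidney"]])      # override despite low counts
  expect_false(e[["thyroid"]])    # 199 in men: below in one sex
  ## exact boundary: 200 qualifies
  e2 <- eligible_sites(data.frame(site = "x", sex = c("M", "F"),
                                  cases = c(200, 200)))
  expect_true(e2[["x"]])
  expect_error(eligible_sites(data.frame(site = "x", sex = "M",
                                         cases = -1)))
})

test_that("the classical ratio matches hand-computed expected counts", {
  rt <- rbind(two_cell_table(ev_t1d = 12, py_t1d = 600,
                             ev_pop = 100, py_pop = 10000),
              two_cell_table(ev_t1d = 8, py_t1d = 400,
                             ev_pop = 250, py_pop = 12500,
                             age = 50, period = 2005))
  expected <- 600 * (100 / 10000) + 400 * (250 / 12500)
  expect_equal(smr(rt), (12 + 8) / expected, tolerance = 1e-12)
  expect_error(smr(rt[rt$duration == "pop", ]), "both cohort and population")
  rt2 <- rt[-2, ]  # cohort stratum without population counterpart
  expect_error(smr(rt2), "missing from the population")
})

test_that("the heterogeneity test needs several countries with events", {
  rt <- two_cell_table(30, 1000, 200, 20000)
  expect_error(heterogeneity_test(rt), "at least two countries")
})

test_that("the heterogeneity test detects a grossly heterogeneous effect", {
  ## two countries simulated with very different true hazard ratios,
  ## fitted as one table
  mk <- function(country, hr, seed) {
    cfg <- sim_config(n = 2500, countries = country,
                      missing_dx_countries = character(0), sexes = c(M = 1))
    eff <- list(all = true_effect("all", binary = hr))
    small_rate_table(cfg, eff, seed = seed)
  }
  rt <- rbind(mk("DK", 1, 301), mk("SE", 4, 302))
  h <- suppressWarnings(heterogeneity_test(rt))
  expect_s3_class(h, "htest")
  expect_equal(unname(h$parameter), 1)
  expect_lt(h$p.value, 1e-4)
})

test_that("the age-at-diagnosis interaction test runs on banded tables", {
  cfg <- sim_config(n = 4000, countries = "SE", sexes = c(M = 1))
  eff <- list(all = true_effect("all", binary = 1.3))
  reg <- simulate_registry(cfg, eff, seed = 311)
  seg <- split_follow_up(reg$cohort, windows = cfg$windows)
  cells <- tabulate_lexis(seg, by_dx_band = TRUE)
  rt <- rate_table(cells, reg$population, site = "all")
  expect_error(age_at_dx_interaction(rt[, setdiff(names(rt), "dx_band")]),
               "dx_band")
  h <- suppressWarnings(age_at_dx_interaction(rt))
  expect_s3_class(h, "htest")
  expect_equal(unname(h$parameter), 2)
  hr <- attr(h, "hr")
  expect_setequal(hr$level, c("t1d:<30", "t1d:30-35", "t1d:35-40"))
  ## a homogeneous truth should rarely reject; at minimum the
  ## statistic must be a valid non-negative chi-square
  expect_gte(unname(h$statistic), 0)
})

test_that("hazard-ratio tables refuse non-converged fits", {
  rt <- two_cell_table(30, 1000, 200, 20000)
  fit <- suppressWarnings(apcfit(rt, diabetes = "binary"))
  fit$converged <- FALSE
  expect_error(hr_table(fit), "non-converged")
})
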