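test_that("person-time is conserved exactly through splitting", {
  cfg <- sim_config(n = 600, countries = c("DK", "SE"))
  eff <- list(all = default_true_effect("all"))
  coh <- simulate_t1d_cohort(cfg, eff, seed = 11)
  seg <- split_follow_up(coh, windows = cfg$windows)
  by_id <- rowsum(seg$pyrs, seg$id)
  expect_equal(as.vector(by_id),
               (coh$exit - coh$entry)[match(as.integer(rownames(by_id)),
                                            coh$id)],
               tolerance = 1e-12)
  ## and in total
  expect_lt(abs(sum(seg$pyrs) - sum(coh$exit - coh$entry)) /
              sum(coh$exit - coh$entry), 1e-9)
})

test_that("splitting matches a day-stepping oracle on every cell", {
  cfg <- sim_config(n = 25, countries = "SC")
  eff <- list(all = default_true_effect("all"))
  coh <- simulate_t1d_cohort(cfg, eff, seed = 21)
  seg <- split_follow_up(coh, windows = cfg$windows)
  b <- duration_bands()
  h <- 1 / 365.25
  oracle <- new.env()
  for (r in seq_len(nrow(coh))) {
    t <- seq(coh$entry[r], coh$exit[r] - h / 2, by = h)
    if (!length(t)) next
    tm <- t + h / 2  # classify each day by its midpoint
    age <- floor(tm - coh$dob[r])
    per <- floor(tm)
    dur <- if (is.na(coh$dx[r])) rep("unknown", length(tm)) else
      b$labels[findInterval(tm - coh$dx[r], b$cuts)]
    key <- paste(age, per, dur)
    for (k in unique(key))
      assign(k, (if (exists(k, oracle)) get(k, oracle) else 0) +
               sum(key == k) * h, oracle)
  }
  got <- rowsum(seg$pyrs, paste(seg$age, seg$period, seg$duration))
  for (k in rownames(got)) {
    o <- if (exists(k, oracle)) get(k, oracle) else 0
    expect_lt(abs(got[k, 1] - o), 3 / 365.25)
  }
})

test_that("refining the break set never changes any aggregate", {
  cfg <- sim_config(n = 300, countries = "FI")
  eff <- list(all = default_true_effect("all"))
  coh <- simulate_t1d_cohort(cfg, eff, seed = 31)
  seg1 <- split_follow_up(coh, windows = cfg$windows)
  seg2 <- split_follow_up(coh, windows = cfg$windows,
                          extra_cuts = c(1980.123, 1990.5, 2001.77))
  t1 <- tabulate_lexis(seg1)
  t2 <- tabulate_lexis(seg2)
  key <- function(d) paste(d$country, d$sex, d$age, d$period, d$duration)
  expect_setequal(key(t1), key(t2))
  m <- match(key(t1), key(t2))
  expect_equal(t1$pyrs, t2$pyrs[m], tolerance = 1e-9)
  expect_identical(t1$events, t2$events[m])
})

test_that("duration never decreases along a person's follow-up", {
  cfg <- sim_config(n = 400, countries = "SE")
  eff <- list(all = default_true_effect("all"))
  coh <- simulate_t1d_cohort(cfg, eff, seed = 41)
  seg <- split_follow_up(coh, windows = cfg$windows)
  lev <- match(seg$duration, duration_bands()$labels)
  ok <- tapply(lev, seg$id, function(x) all(diff(x) >= 0))
  expect_true(all(ok))
})

test_that("each cancer is attributed exactly once, to its own cell", {
  cfg <- sim_config(n = 2000, countries = "DK",
                    missing_dx_countries = character(0))
  eff <- list(all = default_true_effect("all"))
  coh <- simulate_t1d_cohort(cfg, eff, seed = 51)
  seg <- split_follow_up(coh, windows = cfg$windows)
  expect_equal(sum(seg$event), sum(!is.na(coh$cancer_time)))
  ## exactly one event row per cancer, and it contains the event time
  ev <- seg[seg$event == 1, ]
  expect_false(any(duplicated(ev$id)))
  ct <- coh$cancer_time[match(ev$id, coh$id)]
  expect_true(all(floor(ct + 1e-9) == ev$period))
  expect_true(all(ev$age == floor(ct - coh$dob[match(ev$id, coh$id)] + 1e-9)))
})

test_that("site-specific censoring overestimates person-time, all-sites does not", {
  cfg <- sim_config(n = 1500, countries = "FI")
  eff <- list(all = true_effect("all", binary = 2))
  coh <- simulate_t1d_cohort(cfg, eff, seed = 61)
  over <- overestimation_check(coh, windows = cfg$windows)
  expect_gt(over, 0)
  seg_as <- split_follow_up(coh, variant = "all_sites",
                            windows = cfg$windows)
  seg_ss <- split_follow_up(coh, variant = "site_specific",
                            windows = cfg$windows)
  expect_gt(sum(seg_ss$pyrs), sum(seg_as$pyrs))
  expect_error(tabulate_lexis(rbind(seg_as, seg_ss)), "mixed")
})

test_that("tabulation conserves events and person-years", {
  cfg <- sim_config(n = 800, countries = c("AU", "SC"))
  eff <- list(all = default_true_effect("all"))
  coh <- simulate_t1d_cohort(cfg, eff, seed = 71)
  seg <- split_follow_up(coh, windows = cfg$windows)
  cells <- tabulate_lexis(seg)
  expect_equal(sum(cells$pyrs), sum(seg$pyrs), tolerance = 1e-12)
  expect_equal(sum(cells$events), sum(seg$event))
  ## by-dx-band tabulation conserves the same totals
  cells2 <- tabulate_lexis(seg, by_dx_band = TRUE)
  expect_equal(sum(cells2$pyrs), sum(seg$pyrs), tolerance = 1e-12)
  expect_equal(sum(cells2$events), sum(seg$event))
})

test_that("invalid cohorts are refused with informative errors", {
  cfg <- sim_config(n = 50, countries = "DK")
  eff <- list(all = default_true_effect("all"))
  coh <- simulate_t1d_cohort(cfg, eff, seed = 81)
  bad <- coh
  bad$entry[1] <- bad$exit[1] + 1
  expect_error(split_follow_up(bad, windows = cfg$windows),
               "exit precedes entry")
  bad2 <- coh
  bad2$dx[1] <- bad2$entry[1] + 5
  expect_error(split_follow_up(bad2, windows = cfg$windows),
               "entry precedes diabetes diagnosis")
  bad3 <- coh
  bad3$country[1] <- "XX"
  expect_error(split_follow_up(bad3, windows = cfg$windows),
               "missing study window")
})

test_that("the model table stacks cohort cells on population rows", {
  cfg <- flat_config(n = 500)
  eff <- list(all = true_effect("all", binary = 1.5))
  rt <- small_rate_table(cfg, eff, seed = 91)
  expect_true(all(c("pop", "5-10") %in% rt$duration))
  expect_true(all(rt$age < 90))
  expect_true(all(rt$pyrs > 0))
  expect_identical(rt$cohort, rt$period - rt$age)
  pop <- simulate_population_table(make_rate_surface(cfg, "all"),
                                   pop_structure(cfg), seed = 91)
  cells <- tabulate_lexis(split_follow_up(
    simulate_t1d_cohort(cfg, eff, seed = 91), windows = cfg$windows))
  expect_error(rate_table(cells, pop, site = "nosuch"), "unknown site")
})
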