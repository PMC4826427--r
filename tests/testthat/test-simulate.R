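test_that("the time grid telescopes exactly and cuts at every boundary", {
  tg <- t1dapc:::.time_grid
  entry <- c(1995.3, 2000.0, 1997.25)
  exit <- c(2001.7, 2000.0, 1999.0)
  dob <- c(1960.1, 1980.5, 1990.0)
  dx <- c(1990.0, 1999.5, 1996.5)
  g <- tg(entry, exit, dob = dob, dx = dx, dur_cuts = c(1, 2, 5, 10))

  ## person 2 has zero follow-up and contributes no rows
  expect_false(2 %in% g$i)
  ## exact telescoping per person
  for (p in c(1, 3)) {
    gp <- g[g$i == p, ]
    expect_equal(gp$t0[1], entry[p])
    expect_equal(gp$t1[nrow(gp)], exit[p])
    expect_true(all(abs(gp$t0[-1] - gp$t1[-nrow(gp)]) < 1e-12))
    expect_equal(sum(gp$t1 - gp$t0), exit[p] - entry[p])
  }
  ## every interior cut is an integer age, an integer year or a
  ## duration cut
  cuts <- g$t0[duplicated(g$i)]
  near <- function(x, y) abs(x - y) < 1e-9
  ok <- vapply(seq_along(cuts), function(j) {
    p <- g$i[duplicated(g$i)][j]
    t <- cuts[j]
    near(t, round(t)) || near(t - dob[p], round(t - dob[p])) ||
      any(near(t - dx[p], c(1, 2, 5, 10)))
  }, TRUE)
  expect_true(all(ok))
})

test_that("the piecewise-exponential draw reproduces the exponential law", {
  tg <- t1dapc:::.time_grid
  pd <- t1dapc:::.pw_exp_draw
  n <- 20000
  g <- tg(rep(0, n), rep(10, n))
  h <- 0.2
  set.seed(1)
  tt <- pd(g, rep(h, nrow(g)), n)
  ## P(event within 10) = 1 - exp(-2); observed times are truncated
  ## exponentials
  p_ev <- 1 - exp(-h * 10)
  expect_equal(mean(!is.na(tt)), p_ev, tolerance = 0.02)
  emean <- (1 / h - 10 * exp(-h * 10) / p_ev)  # mean of truncated exp
  expect_equal(mean(tt, na.rm = TRUE), emean, tolerance = 0.05)
})

test_that("cohort simulation is deterministic and respects its invariants", {
  cfg <- sim_config(n = 400, countries = c("AU", "DK"), seed = NULL)
  eff <- list(all = default_true_effect("all"))
  a <- simulate_t1d_cohort(cfg, eff, seed = 7)
  b <- simulate_t1d_cohort(cfg, eff, seed = 7)
  expect_identical(a, b)
  c2 <- simulate_t1d_cohort(cfg, eff, seed = 8)
  expect_false(identical(a, c2))

  known <- !is.na(a$dx)
  ## onset strictly below 40, entry never precedes diagnosis
  expect_true(all(a$dx[known] - a$dob[known] < 40))
  expect_true(all(a$entry[known] >= a$dx[known] - 1e-9))
  expect_true(all(a$exit >= a$entry))
  ## cancer and death times lie within follow-up when observed
  ev <- !is.na(a$cancer_time)
  expect_true(all(a$cancer_time[ev] <= a$exit[ev] + 1e-9))
  ## prevalent cases in AU/DK have the diagnosis date withheld
  w0 <- vapply(country_windows()[a$country], `[`, 0, 1)
  expect_true(all(is.na(a$dx) | a$dx >= w0 - 1e-9))
})

test_that("the population table draws Poisson counts at the surface rate", {
  cfg <- flat_config(n = 10)
  surf <- make_rate_surface(cfg, "all")
  structure_ <- pop_structure(cfg)
  set.seed(3)
  pop <- simulate_population_table(surf, structure_)
  expect_equal(nrow(pop), nrow(structure_))
  ## flat surface: empirical rate near rate0 with tight Monte-Carlo SE
  rate_hat <- sum(pop$cases) / sum(pop$person_years)
  expect_equal(rate_hat, 2e-3, tolerance = 0.02)
  expect_true(all(pop$cases >= 0 & pop$cases == round(pop$cases)))
})

test_that("effects must cover the configured sites and nothing else", {
  cfg <- flat_config(n = 50)
  expect_error(simulate_t1d_cohort(cfg, list(), seed = 1),
               "at least one")
  expect_error(
    simulate_t1d_cohort(cfg, list(bladder = true_effect("bladder")),
                        seed = 1),
    "missing: all")
  expect_error(
    simulate_t1d_cohort(cfg, list(all = true_effect("all"),
                                  bladder = true_effect("bladder")),
                        seed = 1),
    "unknown site: bladder")
})

test_that("cohort CSV round-trips through write and read", {
  cfg <- sim_config(n = 120, countries = c("AU", "FI"))
  eff <- list(all = default_true_effect("all"))
  coh <- simulate_t1d_cohort(cfg, eff, seed = 5)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  for (col in c("dob", "dx", "cancer_time", "death_time", "entry", "exit"))
    expect_equal(back[[col]], coh[[col]], tolerance = 1e-8)
  expect_identical(back$cancer_site, coh$cancer_site)
})
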