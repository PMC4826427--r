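test_that("on a single stratum the model reduces to the closed-form rate ratio", {
  rt <- two_cell_table(ev_t1d = 30, py_t1d = 1000,
                       ev_pop = 200, py_pop = 20000)
  fit <- suppressWarnings(apcfit(rt, diabetes = "binary"))
  truth <- (30 / 1000) / (200 / 20000)
  expect_equal(unname(exp(coef(fit)["t1d"])), truth, tolerance = 1e-10)
  expect_equal(unname(exp(coef(fit)["t1d"])), smr(rt), tolerance = 1e-10)
  ## Wald interval uses the usual 1/O1 + 1/O0 variance
  se2 <- 1 / 30 + 1 / 200
  ## the information is evaluated at the numerically converged fit, so
  ## expect agreement to IRLS precision, not machine precision
  expect_equal(unname(fit$vcov["t1d", "t1d"]), se2, tolerance = 1e-4)
})

test_that("hazard-ratio tables apply the Wald construction exactly", {
  rt <- two_cell_table(ev_t1d = 100, py_t1d = 1000,
                       ev_pop = 1000, py_pop = 10000)
  fit <- suppressWarnings(apcfit(rt, diabetes = "binary"))
  ## identical rates: delta = 0, SE = sqrt(1/100 + 1/1000)
  ht <- hr_table(fit)
  expect_equal(ht$hr, 1, tolerance = 1e-8)
  se <- sqrt(1 / 100 + 1 / 1000)
  expect_equal(ht$lo95, exp(-1.96 * se), tolerance = 1e-6)
  expect_equal(ht$hi95, exp(+1.96 * se), tolerance = 1e-6)
})

test_that("a zero-event duration level is flagged as a boundary estimate", {
  rt <- rbind(two_cell_table(ev_t1d = 0, py_t1d = 500,
                             ev_pop = 100, py_pop = 10000),
              within(two_cell_table(ev_t1d = 12, py_t1d = 400,
                                    ev_pop = 90, py_pop = 9000,
                                    age = 40, period = 2005),
                     duration[duration == "5-10"] <- "10-15"))
  w <- testthat::capture_warnings(fit <- apcfit(rt, diabetes = "duration"))
  expect_match(w, "boundary", all = FALSE)
  expect_true(fit$boundary["dur5-10"])
  ht <- hr_table(fit)
  expect_true(is.na(ht$hr[ht$level == "dur5-10"]))
  expect_false(is.na(ht$hr[ht$level == "dur10-15"]))
})

test_that("the delta estimate is invariant to the identifiability constraint", {
  cfg <- sim_config(n = 2500, countries = "FI", sexes = c(M = 1))
  eff <- list(all = true_effect("all", binary = 1.6))
  rt <- small_rate_table(cfg, eff, seed = 201)
  f_c <- suppressWarnings(apcfit(rt, diabetes = "binary",
                                 constraint = "cohort"))
  f_p <- suppressWarnings(apcfit(rt, diabetes = "binary",
                                 constraint = "period"))
  expect_lt(abs(coef(f_c)["t1d"] - coef(f_p)["t1d"]), 1e-6)
  expect_equal(f_c$deviance, f_p$deviance, tolerance = 1e-6)
})

test_that("rescaling person-years moves only the intercepts (offset equivariance)", {
  cfg <- sim_config(n = 1500, countries = "DK", sexes = c(M = 1))
  eff <- list(all = true_effect("all", binary = 1.4))
  rt <- small_rate_table(cfg, eff, seed = 211)
  f1 <- suppressWarnings(apcfit(rt, diabetes = "binary"))
  rt2 <- rt
  rt2$pyrs <- rt2$pyrs * 1000
  f2 <- suppressWarnings(apcfit(rt2, diabetes = "binary",
                                knots = f1$design$knots))
  expect_lt(abs(coef(f1)["t1d"] - coef(f2)["t1d"]), 1e-6)
  ic <- grep("^country:", names(coef(f1)))
  expect_equal(unname(coef(f2)[ic]), unname(coef(f1)[ic]) - log(1000),
               tolerance = 1e-6)
})

test_that("adding knots never increases the deviance", {
  cfg <- sim_config(n = 2500, countries = "SE", sexes = c(M = 1))
  eff <- list(all = default_true_effect("all"))
  rt <- small_rate_table(cfg, eff, seed = 221)
  dev <- vapply(c(0, 2, 5), function(k)
    suppressWarnings(apcfit(rt, diabetes = "binary",
                            n_knots = k,
                            min_per_interval = 1))$deviance, 0)
  expect_true(all(diff(dev) <= 1e-6))
})

test_that("the saturated two-cell fit is exact to the IRLS tolerance", {
  rt <- two_cell_table(ev_t1d = 17, py_t1d = 321.5,
                       ev_pop = 963, py_pop = 54321)
  fit <- suppressWarnings(apcfit(rt, diabetes = "binary"))
  expect_lt(fit$deviance, 1e-8)
  expect_equal(fitted(fit), rt$events, tolerance = 1e-8)
})

test_that("the methods behave like a classic model object", {
  cfg <- sim_config(n = 1200, countries = "DK", sexes = c(M = 1))
  eff <- list(all = default_true_effect("all"))
  rt <- small_rate_table(cfg, eff, seed = 231)
  fit <- suppressWarnings(apcfit(rt, diabetes = "binary"))

  expect_output(print(fit), "Age-period-cohort")
  expect_output(print(summary(fit)), "constraint")
  expect_named(coef(fit))
  expect_equal(dim(vcov(fit)), rep(length(coef(fit)), 2))
  ci <- confint(fit, "t1d")
  expect_true(ci[1] < coef(fit)["t1d"] && coef(fit)["t1d"] < ci[2])
  expect_equal(length(fitted(fit)), nrow(fit$data))
  expect_lt(abs(sum(residuals(fit, "response"))) / sum(fit$y), 1e-8)
  expect_s3_class(logLik(fit), "logLik")

  ## predict: link/response consistency and count scaling
  eta <- predict(fit)
  expect_equal(exp(eta), predict(fit, type = "response"))
  expect_equal(predict(fit, type = "count"),
               predict(fit, type = "response") * fit$data$pyrs)
  ## prediction on a new table evaluates the same basis
  nd <- fit$data[7:11, ]
  expect_equal(predict(fit, nd), eta[7:11])

  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(length(fitted(fit)), 3L))
  expect_true(all(sims >= 0))

  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  grDevices::png(f)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("sex-mixed tables and malformed inputs are refused", {
  rt <- two_cell_table(30, 1000, 200, 20000)
  rt2 <- rt
  rt2$sex <- c("M", "F")
  expect_error(apcfit(rt2), "each sex separately")
  expect_error(apcfit(rt[, -1]), "must have columns")
  expect_error(apcfit(rt, dx_age = TRUE, diabetes = "duration"),
               "binary")
  expect_error(apcfit(rt, dx_age = TRUE), "dx_band")
})
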