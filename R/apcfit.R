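#' Fit the smooth age-period-cohort Poisson rate model
#'
#' Fits the proportional-hazards rate model
#'
#'   log(lambda) = f_n(age) + g_n(period) + h_n(cohort) + delta_d
#'
#' to an events/person-years table by Poisson regression with
#' log person-years offset, where `f_n, g_n, h_n` are per-country
#' natural cubic splines and `delta_d` contrasts the type 1 diabetes
#' cohort (overall, or by duration band) against the smoothly modelled
#' general-population rates.  `exp(delta)` is the hazard ratio and
#' generalises the classical standardised incidence ratio, with the
#' population rates stabilised by smoothing rather than taken
#' empirically in small intervals.
#'
#' Spline knots are placed per country and timescale so the number of
#' cases between consecutive knots is balanced ([balanced_knots()]),
#' with the interior-knot count halved while intervals hold fewer than
#' `min_per_interval` cases.  Fitting is iteratively reweighted least
#' squares ([stats::glm.fit]) run to a relative deviance change below
#' `epsilon` or `maxit` iterations; the covariance is the inverse
#' Fisher information.  Cells with zero person-years are dropped (an
#' offset of `-Inf` is undefined); zero-event cells are retained.
#'
#' @param data Lexis-cell table from [rate_table()]: columns country,
#'   sex (single level), age, period, duration (`"pop"` for the
#'   general-population rows), events, pyrs; `dx_band` when
#'   `dx_age = TRUE`.  Rows with duration `"unknown"` are kept in the
#'   binary model and dropped from the duration model.
#' @param diabetes `"binary"` or `"duration"`.
#' @param n_knots default number of interior knots per timescale per
#'   country.
#' @param knots optional nested list `knots[[country]][[scale]]`
#'   overriding the automatic placement.
#' @param per_country separate delta per country (heterogeneity model).
#' @param dx_age delta per age-at-diagnosis band instead of a common
#'   delta (interaction model); rows lacking the band are dropped.
#' @param constraint identifiability constraint, see [build_design()].
#' @param knot_source which cases the knot rule counts: all events
#'   (default), the cohort's, or the population's.
#' @param min_per_interval sparse-data threshold for knot halving.
#' @param bands a [duration_bands()] object.
#' @param epsilon,maxit IRLS convergence control.
#' @return object of class `apcfit` with components `coefficients`,
#'   `vcov`, `deviance`, `df.residual`, `converged`, `boundary`
#'   (delta levels with zero events), `design` (an `apc_design`), and
#'   the data needed by the methods.  Methods: `print`, `summary`,
#'   `coef`, `vcov`, `confint`, `fitted`, `residuals`, `predict`,
#'   `simulate`, `logLik`, `plot`, and [hr_table()].
#' @export
apcfit <- function(data, diabetes = c("binary", "duration"),
                   n_knots = 5, knots = NULL, per_country = FALSE,
                   dx_age = FALSE, constraint = c("cohort", "period"),
                   knot_source = c("all", "t1d", "pop"),
                   min_per_interval = 50, bands = duration_bands(),
                   epsilon = 1e-8, maxit = 100) {
  diabetes <- match.arg(diabetes)
  constraint <- match.arg(constraint)
  knot_source <- match.arg(knot_source)
  cl <- match.call()
  need <- c("country", "age", "period", "duration", "events", "pyrs")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if ("sex" %in% names(data) && length(unique(data$sex)) > 1)
    stop("fit each sex separately (models are sex-specific)")
  data <- data[data$pyrs > 0, , drop = FALSE]
  if (diabetes == "duration")
    data <- data[data$duration != "unknown", , drop = FALSE]
  if (dx_age) {
    if (diabetes != "binary")
      stop("the age-at-diagnosis interaction applies to the binary model")
    if (!"dx_band" %in% names(data))
      stop("dx_age = TRUE needs a dx_band column (tabulate with by_dx_band)")
    drop <- data$duration != "pop" &
      (is.na(data$dx_band) | data$dx_band == "unknown")
    data <- data[!drop, , drop = FALSE]
    for (b in c("<30", "30-35", "35-40"))
      if (!any(data$dx_band == b & data$duration != "pop", na.rm = TRUE))
        stop("age-at-diagnosis band '", b, "' is empty")
  }
  if (nrow(data) == 0) stop("no usable cells")

  if (is.null(knots))
    knots <- auto_apc_knots(data, n_knots = n_knots,
                            knot_source = knot_source,
                            min_per_interval = min_per_interval)
  desc <- build_design(data, knots, diabetes = diabetes,
                       per_country = per_country, dx_age = dx_age,
                       constraint = constraint, bands = bands)

  X <- desc$X
  off <- log(data$pyrs)
  fit <- suppressWarnings(
    stats::glm.fit(X, data$events, family = stats::poisson(),
                   offset = off,
                   control = stats::glm.control(epsilon = epsilon,
                                                maxit = maxit)))
  if (!fit$converged)
    warning("IRLS did not converge in ", maxit,
            " iterations; partial fit returned")

  beta <- fit$coefficients
  V <- matrix(NA_real_, ncol(X), ncol(X),
              dimnames = list(colnames(X), colnames(X)))
  p1 <- seq_len(fit$rank)
  piv <- fit$qr$pivot[p1]
  V[piv, piv] <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])

  ## separation: a delta level whose cells hold zero events sits on the
  ## likelihood boundary (estimate diverges)
  boundary <- vapply(desc$delta_idx, function(j)
    sum(data$events[X[, j] > 0]) == 0, TRUE)
  names(boundary) <- desc$delta_labels
  if (any(boundary))
    warning("delta level(s) with zero events (boundary estimate): ",
            paste(desc$delta_labels[boundary], collapse = ", "))

  structure(list(coefficients = beta, vcov = V,
                 deviance = fit$deviance,
                 null.deviance = fit$null.deviance,
                 df.residual = fit$df.residual,
                 rank = fit$rank, converged = fit$converged,
                 boundary = boundary, design = desc,
                 diabetes = diabetes, constraint = constraint,
                 y = data$events, offset = off,
                 fitted.values = fit$fitted.values,
                 data = data, call = cl),
            class = "apcfit")
}

## balanced knots for all countries and timescales of a cell table
auto_apc_knots <- function(data, n_knots = 5, knot_source = "all",
                           min_per_interval = 50) {
  sc <- scale_values(data)
  w <- data$events
  if (knot_source == "t1d") w <- w * (data$duration != "pop")
  if (knot_source == "pop") w <- w * (data$duration == "pop")
  out <- list()
  for (cn in sort(unique(data$country))) {
    rows <- data$country == cn
    out[[cn]] <- lapply(stats::setNames(nm = c("age", "period", "cohort")),
                        function(s)
                          .auto_knots(sc[[s]][rows], w[rows],
                                      n_interior = n_knots,
                                      min_per_interval = min_per_interval,
                                      timescale = s))
  }
  out
}

## ---- methods ---------------------------------------------------------------

#' @export
print.apcfit <- function(x, ...) {
  cat("Age-period-cohort Poisson rate model (",
      if (x$diabetes == "binary") "binary type 1 diabetes contrast"
      else "diabetes-duration contrasts", ")\n", sep = "")
  cat(sprintf("  %d cells, %d events, deviance %.2f on %d df%s\n",
              length(x$y), sum(x$y), x$deviance, x$df.residual,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  ht <- tryCatch(hr_table(x), error = function(e) NULL)
  if (!is.null(ht)) {
    cat("  Hazard ratios vs general population:\n")
    print(format(ht, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.apcfit <- function(object, ...) {
  structure(list(fit = object,
                 hr = tryCatch(hr_table(object),
                               error = function(e) NULL)),
            class = "summary.apcfit")
}

#' @export
print.summary.apcfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  constraint: detrended %s basis (delta invariant to this choice)\n",
              x$fit$constraint))
  invisible(x)
}

#' @export
coef.apcfit <- function(object, ...) object$coefficients

#' @export
vcov.apcfit <- function(object, ...) object$vcov

#' @export
confint.apcfit <- function(object, parm, level = 0.95, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(b - z * se, b + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2,
                                       1 - (1 - level) / 2)), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.apcfit <- function(object, ...) object$fitted.values

#' @export
logLik.apcfit <- function(object, ...) {
  ll <- sum(stats::dpois(object$y, object$fitted.values, log = TRUE))
  structure(ll, df = object$rank, nobs = length(object$y),
            class = "logLik")
}

#' @export
residuals.apcfit <- function(object,
                             type = c("deviance", "pearson", "response"),
                             ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted.values
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu),
         deviance = {
           d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
           sign(y - mu) * sqrt(pmax(d, 0))
         })
}

#' Predicted rates from a fitted age-period-cohort model
#'
#' @param object an [apcfit()] object.
#' @param newdata Lexis-cell data.frame (columns country, age, period,
#'   duration, and dx_band when the fit used it); defaults to the
#'   fitting data.
#' @param type `"link"` (log rate per person-year), `"response"` (rate
#'   per person-year) or `"count"` (expected events, requires a `pyrs`
#'   column).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.apcfit <- function(object, newdata = NULL,
                           type = c("link", "response", "count"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  X <- eval_design(object$design, newdata)
  b <- object$coefficients
  b[is.na(b)] <- 0  # aliased columns were dropped from the fit
  eta <- drop(X %*% b)
  switch(type, link = eta, response = exp(eta),
         count = {
           if (is.null(newdata$pyrs)) stop("type='count' needs pyrs")
           exp(eta) * newdata$pyrs
         })
}

#' @export
simulate.apcfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.apcfit <- function(x, ...) {
  if (x$diabetes == "duration") {
    plot_duration_profile(hr_table(x), ...)
  } else {
    d <- x$data[x$data$duration == "pop", , drop = FALSE]
    ## reference period: the observed period closest to the median
    ## (the median itself can fall between two calendar years)
    p_ref <- d$period[which.min(abs(d$period - stats::median(d$period)))]
    d <- d[d$period == p_ref, , drop = FALSE]
    d <- d[order(d$country, d$age), ]
    rate <- predict(x, d, type = "response")
    graphics::plot(d$age, 1e5 * rate, type = "n", log = "y",
                   xlab = "Age (years)",
                   ylab = "Fitted rate per 100,000 person-years",
                   main = paste("Fitted population rates,", p_ref))
    for (cn in unique(d$country))
      graphics::lines(d$age[d$country == cn],
                      1e5 * rate[d$country == cn],
                      col = which(unique(d$country) == cn))
    graphics::legend("topleft", legend = unique(d$country),
                     col = seq_along(unique(d$country)), lty = 1,
                     bty = "n")
    invisible(x)
  }
}
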