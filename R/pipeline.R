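#' Desk-scale demonstration configuration
#'
#' A reduced synthetic registry for end-to-end runs: three countries,
#' two sites (a bulk "carcinoma" site and kidney, which illustrates the
#' eligibility override), both sexes, and an eligibility threshold
#' scaled to the demo's case counts (the analysis default of 200
#' remains the package default elsewhere).
#'
#' @param n cohort size.
#' @return a [sim_config()] object.
#' @export
demo_config <- function(n = 25000) {
  sim_config(
    n = n, countries = c("DK", "FI", "SE"),
    sites = list(
      carcinoma = list(rate0 = 3.2e-4, ref_age = 25, age_slope = 0.085,
                       period_drift = 0.01),
      kidney = list(rate0 = 0.8e-4, ref_age = 25, age_slope = 0.085,
                    period_drift = 0.005)),
    min_cases = 50)
}

## population rows summed over sites, for the all-cancers analyses
pop_all_sites <- function(pop) {
  key <- paste(pop$country, pop$sex, pop$age, pop$period, sep = "\r")
  first <- !duplicated(key)
  out <- pop[first, c("country", "sex", "age", "period", "person_years")]
  out$site <- "all"
  out$cases <- as.vector(rowsum(pop$cases, key, reorder = FALSE))
  out
}

#' Run the full simulate - split - tabulate - fit pipeline
#'
#' Executes every stage in order for both censoring variants and both
#' diabetes parametrisations, and writes the output bundle: person and
#' population CSVs, Lexis-cell CSVs, binary- and duration-model
#' hazard-ratio CSVs, heterogeneity-test JSON, duration-profile
#' figures and a run manifest with file digests.  Any stage failure
#' aborts with the stage name and cause.
#'
#' @param config a [sim_config()] object.
#' @param effects named list of [true_effect()] objects (defaults to
#'   the declining duration profile of [default_true_effect()] for
#'   every configured site).
#' @param seed integer seed driving the whole run.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the fitted objects, the HR tables,
#'   the test results and the manifest.
#' @export
run_pipeline <- function(config = demo_config(), effects = NULL,
                         seed = 1, out_dir = tempfile("t1dapc_run_")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(effects))
    effects <- stats::setNames(
      lapply(names(config$sites), default_true_effect), names(config$sites))

  reg <- stage("simulate", {
    r <- simulate_registry(config, effects, seed = seed)
    write_cohort_csv(r$cohort, file.path(out_dir, "person.csv"))
    utils::write.csv(r$population, file.path(out_dir, "population.csv"),
                     row.names = FALSE)
    message(sprintf("simulate: %d persons, %d cohort cancers, %.0f population cases",
                    nrow(r$cohort), sum(!is.na(r$cohort$cancer_site)),
                    sum(r$population$cases)))
    r
  })

  cells <- stage("split", {
    seg_as <- split_follow_up(reg$cohort, variant = "all_sites",
                              windows = config$windows,
                              age_max = config$age_max)
    seg_ss <- split_follow_up(reg$cohort, variant = "site_specific",
                              windows = config$windows,
                              age_max = config$age_max)
    as_ <- tabulate_lexis(seg_as)
    ss <- tabulate_lexis(seg_ss)
    utils::write.csv(as_, file.path(out_dir, "lexis_all_sites.csv"),
                     row.names = FALSE)
    utils::write.csv(ss, file.path(out_dir, "lexis_site_specific.csv"),
                     row.names = FALSE)
    message(sprintf("split: %.1f thousand cohort person-years, %d events (all-sites); overestimation of site-specific person-time %.2f%%",
                    sum(as_$pyrs) / 1e3, sum(as_$events),
                    100 * overestimation_check(reg$cohort,
                                               windows = config$windows,
                                               age_max = config$age_max)))
    list(as = as_, ss = ss)
  })

  pop <- reg$population
  pop_all <- pop_all_sites(pop)
  sexes <- names(config$sexes)
  fits <- list(); hrb <- list(); hrd <- list(); tests <- list()
  stage("fit", {
    t1d_ev <- cells$ss[cells$ss$duration != "pop", , drop = FALSE]
    t1d_counts <- stats::aggregate(cases ~ site + sex,
                                   data = data.frame(site = t1d_ev$site,
                                                     sex = t1d_ev$sex,
                                                     cases = t1d_ev$events),
                                   FUN = sum)
    elig <- eligible_sites(t1d_counts, min_cases = config$min_cases)
    for (sx in sexes) {
      rt_all <- rate_table(cells$as, pop_all, site = "all", sex = sx,
                           age_max = config$age_max)
      fb <- suppressWarnings(apcfit(rt_all, diabetes = "binary"))
      fd <- suppressWarnings(apcfit(rt_all, diabetes = "duration"))
      fits[[paste0("all.", sx)]] <- list(binary = fb, duration = fd)
      hrb[[paste0("all.", sx)]] <- cbind(site = "all", sex = sx,
                                         hr_table(fb))
      hrd[[paste0("all.", sx)]] <- cbind(site = "all", sex = sx,
                                         hr_table(fd))
      if (length(config$countries) >= 2)
        tests[[paste0("heterogeneity.", sx)]] <- tryCatch({
          h <- suppressWarnings(heterogeneity_test(rt_all))
          list(sex = sx, statistic = unname(h$statistic),
               df = unname(h$parameter), p = h$p.value)
        }, error = function(e) NULL)
      for (s in names(config$sites)) {
        rt <- rate_table(cells$ss, pop, site = s, sex = sx,
                         age_max = config$age_max)
        fbs <- suppressWarnings(apcfit(rt, diabetes = "binary"))
        hrb[[paste(s, sx)]] <- cbind(site = s, sex = sx, hr_table(fbs))
        if (isTRUE(elig[s])) {
          fds <- suppressWarnings(apcfit(rt, diabetes = "duration"))
          hrd[[paste(s, sx)]] <- cbind(site = s, sex = sx,
                                       hr_table(fds))
        }
      }
    }
    message(sprintf("fit: %d binary and %d duration hazard-ratio tables",
                    length(hrb), length(hrd)))
  })

  hr_binary <- do.call(rbind, c(hrb, make.row.names = FALSE))
  hr_duration <- do.call(rbind, c(hrd, make.row.names = FALSE))
  stage("report", {
    utils::write.csv(hr_binary, file.path(out_dir, "hr_binary.csv"),
                     row.names = FALSE)
    utils::write.csv(hr_duration, file.path(out_dir, "hr_duration.csv"),
                     row.names = FALSE)
    jsonlite::write_json(tests[!vapply(tests, is.null, TRUE)],
                         file.path(out_dir, "tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (sx in sexes)
      try(plot_duration_profile(
        hr_table(fits[[paste0("all.", sx)]]$duration),
        file = file.path(out_dir, paste0("duration_profile_", sx, ".png")),
        main = paste("All cancers, sex", sx)), silent = TRUE)
  })

  manifest <- stage("manifest", {
    cfg_file <- tempfile()
    dput(unclass(config), cfg_file)
    files <- list.files(out_dir, full.names = TRUE)
    m <- list(seed = seed,
              config_md5 = unname(tools::md5sum(cfg_file)),
              package_version = as.character(utils::packageVersion("t1dapc")),
              files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                              basename(files))))
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    unlink(cfg_file)
    m
  })

  invisible(list(out_dir = out_dir, fits = fits, hr_binary = hr_binary,
                 hr_duration = hr_duration, tests = tests,
                 manifest = manifest))
}
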