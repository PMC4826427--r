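#' Load the published five-country summary table
#'
#' The package ships, as plain CSV fixtures, the published summary of
#' cancer cases and cohort person-years in persons with diabetes
#' diagnosed under age 40, by site, sex and country (Australia,
#' Denmark, Finland, Scotland, Sweden).  Cells are stored verbatim as
#' printed; `NA` marks country/site combinations with no available
#' data.  Person-years (in thousands) come in two variants: `"a"`
#' (follow-up to the first primary tumour of any kind or study end)
#' and `"b"` (follow-up to death or study end, the denominator of the
#' site-specific analyses).
#'
#' @return list of class `table1_fixture` with data.frames `cases`
#'   (site, sex, AU, DK, FI, SC, SE, subtotal, total) and `pyrs`
#'   (variant, sex, AU, ..., subtotal, total).
#' @export
load_table1 <- function() {
  path <- function(f) system.file("extdata", f, package = "t1dapc",
                                  mustWork = TRUE)
  structure(list(cases = utils::read.csv(path("table1_cases.csv"),
                                         stringsAsFactors = FALSE),
                 pyrs = utils::read.csv(path("table1_pyrs.csv"),
                                        stringsAsFactors = FALSE)),
            class = "table1_fixture")
}

#' Reference headline results
#'
#' Published headline quantities (total cancers, cancers with a known
#' diagnosis date, selected hazard ratios) used for derived consistency
#' checks.
#'
#' @return named numeric vector.
#' @export
reference_results <- function() {
  d <- utils::read.csv(system.file("extdata", "reference_results.csv",
                                   package = "t1dapc", mustWork = TRUE),
                       stringsAsFactors = FALSE)
  stats::setNames(d$value, d$quantity)
}

#' Consistency checks on the summary-table fixture
#'
#' Recomputes every row and column sum of the fixture and compares it
#' with the printed marginal: per (site, sex) the country cells against
#' the printed sex subtotal, per site the sex subtotals against the
#' printed total, and the person-years analogues (to the printed 0.1
#' precision).  Derived percentages are also recomputed.  Two printed
#' inconsistencies are expected to flag: the variant-a person-years
#' subtotals (which do not equal the sums of their printed cells), and
#' the men's multiple-myeloma subtotal.
#'
#' @param fixture a [load_table1()] fixture (possibly perturbed, e.g.
#'   as a negative control).
#' @param refs reference quantities from [reference_results()].
#' @return data.frame: check, expected, computed, pass.
#' @export
table1_checks <- function(fixture = load_table1(),
                          refs = reference_results()) {
  ctry <- c("AU", "DK", "FI", "SC", "SE")
  rows <- list()
  add <- function(check, expected, computed, tol = 0) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, expected = expected, computed = computed,
      pass = is.finite(computed) & abs(computed - expected) <= tol + 1e-9,
      stringsAsFactors = FALSE)
  }
  cs <- fixture$cases
  for (i in seq_len(nrow(cs)))
    add(sprintf("cases[%s,%s]: country cells vs subtotal",
                cs$site[i], cs$sex[i]),
        cs$subtotal[i],
        sum(unlist(cs[i, ctry]), na.rm = TRUE))
  for (s in unique(cs$site))
    add(sprintf("cases[%s]: sex subtotals vs total", s),
        cs$total[cs$site == s][1],
        sum(cs$subtotal[cs$site == s]))
  py <- fixture$pyrs
  for (i in seq_len(nrow(py)))
    add(sprintf("pyrs[%s,%s]: country cells vs subtotal",
                py$variant[i], py$sex[i]),
        py$subtotal[i], sum(unlist(py[i, ctry])), tol = 0.05)
  for (v in unique(py$variant))
    add(sprintf("pyrs[%s]: sex subtotals vs total", v),
        py$total[py$variant == v][1],
        sum(py$subtotal[py$variant == v]), tol = 0.05)
  ## derived printed quantities
  tot <- sum(cs$subtotal[cs$site == "all_sites"])
  add("derived: % of cohort cancers with known diagnosis date",
      85.2, round(100 * refs[["cancers_with_known_dx"]] / tot, 1),
      tol = 0.05)
  add("derived: % prostate reduction in men",
      44, 100 * (1 - refs[["prostate_hr_men"]]), tol = 0.5)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.table1_fixture <- function(x, ...) {
  cat("Published summary-table fixture:", nrow(x$cases),
      "case rows,", nrow(x$pyrs), "person-year rows\n")
  invisible(x)
}
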