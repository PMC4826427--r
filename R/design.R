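#' Build the age-period-cohort design matrix
#'
#' One row per Lexis cell.  Per country the design holds an intercept
#' and natural cubic spline bases in age, period and cohort evaluated
#' at the cell midpoints (`a + 0.5`, `p + 0.5`, `c = p - a`), plus
#' indicator columns for the diabetes term (general population is the
#' reference, so population rows have all-zero delta columns).
#'
#' Because age, period and cohort are exactly linearly dependent
#' (`c = p - a`), one spline basis must be constrained for the model to
#' be identified.  The basis named by `constraint` is detrended per
#' country: its person-years-weighted projection onto `{1, x}` is
#' removed, absorbing the drift into the remaining terms.  The choice
#' is recorded in the result and is immaterial to the delta contrasts,
#' which are within-stratum comparisons.
#'
#' @param data Lexis-cell data.frame (see [rate_table()]): columns
#'   country, age, period, duration, events, pyrs (and dx_band when
#'   `dx_age = TRUE`).
#' @param knots nested list `knots[[country]][[scale]]` of
#'   [balanced_knots()] objects (`NULL` entries drop that basis, e.g.
#'   on degenerate data).
#' @param diabetes `"binary"` (single contrast) or `"duration"` (one
#'   contrast per duration band).
#' @param per_country separate delta per country.
#' @param dx_age replace the common binary delta by one delta per
#'   age-at-diagnosis band (`<30`, `30-35`, `35-40`).
#' @param constraint which basis to detrend: `"cohort"` (default) or
#'   `"period"`.
#' @param bands a [duration_bands()] object.
#' @return object of class `apc_design`: list with the model matrix
#'   `X`, `delta_idx`/`delta_labels`, and the knots, constraint and
#'   projection coefficients needed to evaluate the same basis on new
#'   data.
#' @export
build_design <- function(data, knots, diabetes = c("binary", "duration"),
                         per_country = FALSE, dx_age = FALSE,
                         constraint = c("cohort", "period"),
                         bands = duration_bands()) {
  diabetes <- match.arg(diabetes)
  constraint <- match.arg(constraint)
  countries <- sort(unique(data$country))

  ## projection coefficients for the constrained basis, computed from
  ## this data's person-years weights and reused verbatim on new data
  gammas <- list(); con_keep <- list()
  x_con <- scale_values(data)[[constraint]]
  for (cn in countries) {
    kv <- knots[[cn]][[constraint]]
    if (is.null(kv)) next
    rows <- which(data$country == cn)
    B <- ns_basis(x_con[rows], kv)
    Z <- cbind(1, x_con[rows])
    w <- data$pyrs[rows]
    G <- solve(crossprod(Z, w * Z), crossprod(Z, w * B))
    gammas[[cn]] <- G
    ## projecting out {1, x} reduces the spanned dimension by 2 while
    ## the basis keeps its column count, so one column (two, counting
    ## the linear no-interior-knot case) is redundant; drop it here
    Bd <- B - Z %*% G
    q <- qr(Bd)
    con_keep[[cn]] <- sort(q$pivot[seq_len(q$rank)])
  }

  desc <- structure(list(knots = knots, constraint = constraint,
                         gammas = gammas, con_keep = con_keep,
                         countries = countries,
                         diabetes = diabetes, per_country = per_country,
                         dx_age = dx_age, bands = bands),
                    class = "apc_design")
  desc$X <- eval_design(desc, data)
  dl <- attr(desc$X, "delta_labels")
  desc$delta_idx <- which(colnames(desc$X) %in% dl)
  desc$delta_labels <- dl
  r <- qr(desc$X)$rank
  if (r < ncol(desc$X))
    warning("design matrix is rank deficient beyond the age-period-cohort ",
            "redundancy (", ncol(desc$X) - r,
            " aliased columns); they will be dropped in fitting")
  desc
}

scale_values <- function(data) {
  a <- data$age + 0.5
  p <- data$period + 0.5
  list(age = a, period = p, cohort = p - a)
}

## evaluate a natural cubic spline basis from a knot_vector; with no
## interior knots the basis degenerates to a single linear column
ns_basis <- function(x, kv) {
  if (length(kv$knots) == 0)
    matrix(x - kv$boundary[1], ncol = 1)
  else
    unclass(splines::ns(x, knots = kv$knots,
                        Boundary.knots = kv$boundary))
}

## Evaluate the design matrix described by `desc` on `data`.
eval_design <- function(desc, data) {
  n <- nrow(data)
  sc <- scale_values(data)
  blocks <- list()
  ## per-country intercepts
  ci <- vapply(desc$countries, function(cn) as.numeric(data$country == cn),
               numeric(n))
  ci <- matrix(ci, nrow = n,
               dimnames = list(NULL, paste0("country:", desc$countries)))
  blocks$country <- ci
  for (cn in desc$countries) {
    rows <- which(data$country == cn)
    for (s in c("age", "period", "cohort")) {
      kv <- desc$knots[[cn]][[s]]
      if (is.null(kv)) next
      B <- matrix(0, n, if (length(kv$knots) == 0) 1 else
        length(kv$knots) + 1)
      if (length(rows)) {
        Br <- ns_basis(sc[[s]][rows], kv)
        if (s == desc$constraint && !is.null(desc$gammas[[cn]])) {
          Z <- cbind(1, sc[[s]][rows])
          Br <- Br - Z %*% desc$gammas[[cn]]
        }
        B[rows, ] <- Br
      }
      colnames(B) <- paste0(cn, ":", s, seq_len(ncol(B)))
      if (s == desc$constraint && !is.null(desc$con_keep[[cn]]))
        B <- B[, desc$con_keep[[cn]], drop = FALSE]
      if (ncol(B) == 0) next
      blocks[[paste0(cn, ":", s)]] <- B
    }
  }

  ## diabetes term: indicators, general population = reference
  t1d <- data$duration != "pop"
  if (desc$diabetes == "binary") {
    if (desc$dx_age) {
      lv <- c("<30", "30-35", "35-40")
      D <- vapply(lv, function(b)
        as.numeric(t1d & !is.na(data$dx_band) & data$dx_band == b),
        numeric(n))
      D <- matrix(D, nrow = n, dimnames = list(NULL, paste0("t1d:", lv)))
    } else if (desc$per_country) {
      D <- vapply(desc$countries, function(cn)
        as.numeric(t1d & data$country == cn), numeric(n))
      D <- matrix(D, nrow = n,
                  dimnames = list(NULL, paste0("t1d:", desc$countries)))
    } else {
      D <- matrix(as.numeric(t1d), ncol = 1, dimnames = list(NULL, "t1d"))
    }
  } else {
    lv <- desc$bands$labels
    if (desc$per_country) {
      cmb <- expand.grid(b = lv, cn = desc$countries,
                         stringsAsFactors = FALSE)
      D <- mapply(function(b, cn)
        as.numeric(data$duration == b & data$country == cn),
        cmb$b, cmb$cn)
      D <- matrix(D, nrow = n,
                  dimnames = list(NULL, paste0("dur", cmb$b, ":", cmb$cn)))
    } else {
      D <- vapply(lv, function(b) as.numeric(data$duration == b),
                  numeric(n))
      D <- matrix(D, nrow = n, dimnames = list(NULL, paste0("dur", lv)))
    }
  }
  blocks$delta <- D
  X <- do.call(cbind, blocks)
  attr(X, "delta_labels") <- colnames(D)
  X
}
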