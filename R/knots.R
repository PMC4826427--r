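#' Case-balanced spline knots
#'
#' Places interior knots so the number of cases between consecutive
#' knots is the same: the interior knots are the `j/k` quantiles
#' (`j = 1, ..., k-1`) of the event-weighted distribution of the
#' timescale value, with boundary knots at the observed range.  Type-1
#' (left-continuous inverse CDF) quantiles are used, so exact ties sit
#' at a knot and are assigned to the lower interval; with distinct
#' event values the between-knot counts differ by at most 1.
#'
#' @param values timescale values at which events occurred (e.g. cell
#'   midpoints).
#' @param k number of inter-knot intervals (so `k - 1` interior knots).
#' @param weights optional non-negative event counts per value.
#' @param timescale optional label ("age", "period" or "cohort").
#' @return object of class `knot_vector`: list with `timescale`,
#'   `knots` (interior, possibly empty) and `boundary` (length 2).
#' @export
balanced_knots <- function(values, k, weights = NULL, timescale = NULL) {
  stopifnot(k >= 1)
  if (is.null(weights)) weights <- rep(1, length(values))
  keep <- weights > 0 & is.finite(values)
  values <- values[keep]; weights <- weights[keep]
  nd <- length(unique(values))
  if (nd < k + 1)
    stop("degenerate knots: need at least k+1 = ", k + 1,
         " distinct event values, got ", nd)
  o <- order(values)
  v <- values[o]; w <- weights[o]
  cw <- cumsum(w); W <- cw[length(cw)]
  qtype1 <- function(p) v[which(cw >= p * W - 1e-12)[1]]
  interior <- if (k >= 2) vapply(seq_len(k - 1) / k, qtype1, 0) else numeric(0)
  bnd <- range(v)
  interior <- unique(interior)
  interior <- interior[interior > bnd[1] & interior < bnd[2]]
  structure(list(timescale = timescale, knots = interior, boundary = bnd),
            class = "knot_vector")
}

#' @export
print.knot_vector <- function(x, ...) {
  cat("knot_vector", if (!is.null(x$timescale)) paste0("[", x$timescale, "]"),
      "\n  boundary:", format(x$boundary), "\n  interior:",
      if (length(x$knots)) format(x$knots) else "(none)", "\n")
  invisible(x)
}

## Event-balanced knots for one country/timescale with sparse-data
## fallback: the interior-knot count is halved while there are fewer
## than `min_per_interval` events per interval, and NULL is returned
## when the scale is degenerate (fewer than 2 distinct event values).
.auto_knots <- function(values, weights, n_interior = 5,
                        min_per_interval = 50, timescale = NULL) {
  tot <- sum(weights)
  nd <- length(unique(values[weights > 0]))
  if (nd < 2) return(NULL)
  ni <- n_interior
  while (ni > 0 && tot / (ni + 1) < min_per_interval)
    ni <- ni %/% 2
  ni <- min(ni, nd - 2)
  if (ni < 0) ni <- 0
  if (ni == 0)
    return(structure(list(timescale = timescale, knots = numeric(0),
                          boundary = range(values[weights > 0])),
                     class = "knot_vector"))
  balanced_knots(values, k = ni + 1, weights = weights,
                 timescale = timescale)
}
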