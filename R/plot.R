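#' Plot a hazard-ratio profile by diabetes duration
#'
#' Point-and-interval plot of the duration-band hazard ratios from a
#' duration-model [hr_table()], on a logarithmic HR axis, with bands
#' plotted in band order regardless of the input row order.
#'
#' @param hr data.frame from [hr_table()] of a duration model (levels
#'   `dur<band>`).
#' @param file optional output file; `.png` or `.svg` by extension.
#'   `NULL` draws on the current device.
#' @param bands a [duration_bands()] object (for ordering and the
#'   x positions).
#' @param main plot title.
#' @return invisibly, the plotted data in band order.
#' @export
plot_duration_profile <- function(hr, file = NULL,
                                  bands = duration_bands(),
                                  main = "Hazard ratio by diabetes duration") {
  if (nrow(hr) == 0) stop("empty hazard-ratio table")
  lab <- sub("^dur", "", hr$level)
  keep <- lab %in% bands$labels
  hr <- hr[keep, , drop = FALSE]
  lab <- lab[keep]
  if (nrow(hr) == 0) stop("no duration-band levels in the table")
  hr <- hr[order(match(lab, bands$labels)), , drop = FALSE]
  lab <- lab[order(match(lab, bands$labels))]
  ## x position: band midpoint (open last band drawn 5 years wide)
  cuts <- bands$cuts
  mids <- c((cuts[-length(cuts)] + cuts[-1]) / 2,
            cuts[length(cuts)] + 2.5)
  x <- mids[match(lab, bands$labels)]

  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 5)
    else grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  fin <- is.finite(hr$hr)
  ylim <- range(c(hr$lo95[fin], hr$hi95[fin], 1), na.rm = TRUE)
  graphics::plot(x, hr$hr, log = "y", ylim = ylim, pch = 19,
                 xlab = "Duration of diabetes (years)",
                 ylab = "Hazard ratio (log scale)", main = main)
  graphics::abline(h = 1, lty = 3)
  graphics::segments(x, hr$lo95, x, hr$hi95)
  graphics::axis(1, at = bands$cuts, labels = FALSE, tcl = -0.2)
  invisible(hr)
}
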