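#' DSE plot: A, D, S, E curves with flagged-scan stripes
#'
#' The standard visual QC summary: the four whole-brain sum-of-squares
#' series on a common axis (A at t; D and S at t + 1/2; the edge term at the
#' two ends), with a right-hand axis in percent of average A-var. For clean,
#' temporally independent data D and S converge at about 50% of A-var;
#' divergence indicates temporal autocorrelation, and D spikes indicate
#' artifacts. If an inference result is supplied, statistically significant
#' pairs are striped in gray and practically significant ones in orange.
#'
#' @param x a `dse_series`.
#' @param inference optional `dse_inference` for the flag stripes.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.dse_series <- function(x, inference = NULL, main = "DSE decomposition",
                            ...) {
  w <- x$whole
  A <- x$averages$whole$A
  ylim <- range(0, w$A, w$D, w$S)
  graphics::plot(NA, xlim = c(1, x$T), ylim = ylim, xlab = "scan",
                 ylab = "sum of squares", main = main, ...)
  if (!is.null(inference)) {
    fl <- attr(inference, "flagged_pairs")
    if (nrow(fl)) {
      col <- ifelse(fl$practical, grDevices::adjustcolor("orange", 0.5),
                    grDevices::adjustcolor("gray40", 0.35))
      graphics::rect(fl$t, ylim[1], fl$t_plus_1, ylim[2], col = col,
                     border = NA)
    }
  }
  graphics::lines(x$abscissa$A, w$A, col = "forestgreen")
  graphics::lines(x$abscissa$D, w$D, col = "blue3")
  graphics::lines(x$abscissa$S, w$S, col = "goldenrod2")
  edge <- c(1L, x$T)
  graphics::points(edge, w$E[edge], col = "purple3", pch = 16)
  graphics::axis(4, at = pretty(ylim),
                 labels = sprintf("%.0f%%", 100 * pretty(ylim) / A))
  graphics::legend("topright", bty = "n", lwd = c(1, 1, 1, NA),
                   pch = c(NA, NA, NA, 16),
                   col = c("forestgreen", "blue3", "goldenrod2", "purple3"),
                   legend = c("A (total)", "D (fast)", "S (slow)", "E (edge)"))
  invisible(x)
}
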