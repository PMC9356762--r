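#' Plot observed counts against prediction bounds
#'
#' Base-graphics view of one stratum's weekly excess table: observed counts,
#' expected baseline, and the two-sided prediction band, with flagged weeks
#' highlighted.
#'
#' @param tbl a weekly excess table from [excessTable()] or [runAnalysis()].
#' @param main plot title.
#' @param ... passed to [plot()].
#' @return invisibly, `tbl`.
#' @export
plotExcess <- function(tbl, main = "Observed vs. expected weekly deaths",
                       ...) {
  x <- tbl$week_start
  ylim <- range(tbl$observed, tbl$lower, tbl$upper)
  plot(x, tbl$observed, type = "n", xlab = "week", ylab = "deaths",
       ylim = ylim, main = main, ...)
  graphics::polygon(c(x, rev(x)), c(tbl$upper, rev(tbl$lower)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(x, tbl$expected, col = "steelblue", lwd = 2)
  graphics::lines(x, tbl$observed, col = "grey20")
  flagged <- tbl$flag != "NONE"
  if (any(flagged))
    graphics::points(x[flagged], tbl$observed[flagged], pch = 19,
                     col = ifelse(tbl$flag[flagged] == "EXCESS",
                                  "firebrick", "darkorange"))
  invisible(tbl)
}
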