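## Reporting-delay adjustment of provisional counts.
##
## Recent weeks' counts are provisional: deaths are registered with delay,
## so the last ~3 months undercount. A reporting triangle (counts by event
## week and delay) yields an empirical completeness curve; provisional weeks
## are inflated by its reciprocal. This is a deliberately simple
## multiplicative nowcast, bypassable in the pipeline.

#' Construct a ReportingTriangle
#'
#' @param weekStart event-week Mondays.
#' @param counts matrix (rows = event weeks, columns = delays 0..D); `NA`
#'   marks not-yet-observable cells.
#' @return a [ReportingTriangle-class].
#' @export
reportingTriangle <- function(weekStart, counts) {
  counts <- as.matrix(counts)
  colnames(counts) <- paste0("d", seq_len(ncol(counts)) - 1L)
  new("ReportingTriangle", weekStart = as.Date(weekStart), counts = counts)
}

#' Read a reporting triangle from delimited text
#'
#' Long format with header `event_week,delay_weeks,count`. Cells absent from
#' the file are `NA` (not yet observable); the delay range is 0..max stated.
#'
#' @param path file path.
#' @return a [ReportingTriangle-class].
#' @export
readReportingTriangle <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("event_week", "delay_weeks", "count") %in% names(tab)))
  wk <- sort(unique(as.Date(tab$event_week)))
  D <- max(tab$delay_weeks)
  m <- matrix(NA_real_, nrow = length(wk), ncol = D + 1L)
  i <- match(as.Date(tab$event_week), wk)
  m[cbind(i, tab$delay_weeks + 1L)] <- tab$count
  reportingTriangle(wk, m)
}

#' Empirical reporting completeness by delay
#'
#' For each delay d, the fraction of final counts already reported within d
#' weeks, pooled over fully observed event weeks:
#' \eqn{\hat c_d = \sum_i C_{i,d} / \sum_i C_{i,D}} where \eqn{C_{i,d}} is
#' week i's cumulative count at delay d. Nondecreasing in d with
#' \eqn{\hat c_D = 1} by construction.
#'
#' @param tri a [ReportingTriangle-class].
#' @return numeric vector of completeness fractions, names `d0`..`dD`.
#' @export
estimateCompleteness <- function(tri) {
  cnt <- counts(tri)
  full <- stats::complete.cases(cnt)
  if (!any(full))
    stop("no fully observed event week in the reporting triangle")
  cum <- t(apply(cnt[full, , drop = FALSE], 1, cumsum))
  tot <- sum(cum[, ncol(cum)])
  if (tot <= 0) stop("reporting triangle has no reported deaths")
  cd <- colSums(cum) / tot
  names(cd) <- colnames(cnt)
  cd
}

#' Adjust provisional weekly counts for reporting delay
#'
#' Weeks with observable delay `d = as_of week - event week < D` are
#' inflated to `count / c_d` (rounded to the nearest integer, never below
#' the observed count) and flagged provisional; older weeks are unchanged.
#' Weeks after `as_of` are dropped.
#'
#' @param series a [WeeklyCounts-class] of provisional counts.
#' @param completeness completeness fractions from [estimateCompleteness()]
#'   (or a [ReportingTriangle-class], from which they are estimated).
#' @param asOf the data-cut week (date).
#' @return list with `series` (adjusted [WeeklyCounts-class]) and
#'   `provisional` (logical per week).
#' @export
adjustProvisional <- function(series, completeness, asOf) {
  if (methods::is(completeness, "ReportingTriangle"))
    completeness <- estimateCompleteness(completeness)
  D <- length(completeness) - 1L
  asOf <- weekIndex(as.Date(asOf))
  keep <- weekIndex(weekStarts(series)) <= asOf
  ws <- weekStarts(series)[keep]
  y <- counts(series)[keep]
  d <- asOf - weekIndex(ws)
  prov <- d < D
  if (any(prov)) {
    cd <- completeness[d[prov] + 1L]
    if (any(cd <= 0))
      stop("zero estimated completeness at delay ",
           paste(d[prov][cd <= 0], collapse = ", "))
    y[prov] <- pmax(y[prov], as.integer(round(y[prov] / cd)))
  }
  list(
    series = weeklyCounts(ws, y, cause = series@cause, place = series@place,
                          region = series@region),
    provisional = prov
  )
}
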