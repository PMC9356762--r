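## Excess / exiguous death quantification.
##
## A week is flagged EXCESS when the observed count strictly exceeds the
## upper prediction bound and EXIGUOUS when it falls strictly below the
## lower bound. Excess (exiguous) deaths are reported as a range: from the
## distance to the bound (0 if not exceeded) up to the distance to the
## expected count (0 if on the other side). Unflagged weeks therefore still
## contribute their observed-minus-expected surplus to the high endpoint,
## which is what makes cumulative ranges like "0-3179" over unflagged
## periods possible.

#' Flag a week as excess, exiguous, or neither
#'
#' @param observed observed count(s).
#' @param lower,upper prediction bounds.
#' @return character: `"EXCESS"` (observed > upper), `"EXIGUOUS"`
#'   (observed < lower), else `"NONE"`; boundary equality is `"NONE"`.
#' @export
flagWeek <- function(observed, lower, upper) {
  ifelse(observed > upper, "EXCESS",
         ifelse(observed < lower, "EXIGUOUS", "NONE"))
}

#' Weekly excess/exiguous range
#'
#' Excess range: `[max(0, observed - upper), max(0, observed - expected)]`;
#' exiguous range (mirror image): `[max(0, lower - observed),
#' max(0, expected - observed)]`.
#'
#' @param observed,expected,lower,upper vectors of equal length.
#' @return data.frame with columns `excess_low`, `excess_high`,
#'   `exiguous_low`, `exiguous_high`.
#' @export
excessRange <- function(observed, expected, lower, upper) {
  data.frame(
    excess_low = pmax(0, observed - upper),
    excess_high = pmax(0, observed - expected),
    exiguous_low = pmax(0, lower - observed),
    exiguous_high = pmax(0, expected - observed)
  )
}

#' Excess/exiguous percentage
#'
#' Each endpoint of a deaths range divided by the expected count, as a
#' percentage: `100 * deaths / expected`.
#'
#' @param range numeric vector `c(low, high)` or a two-column matrix.
#' @param expected expected count(s), must be positive.
#' @return same shape as `range`, in percent.
#' @examples
#' excessPercentage(c(689, 2161), 2161 / 0.0858)
#' @export
excessPercentage <- function(range, expected) {
  if (any(expected <= 0)) stop("expected must be positive")
  100 * range / expected
}

#' Weekly excess table for one stratum
#'
#' Joins observations to baseline estimates and computes flags, ranges, and
#' percentage ranges.
#'
#' @param series a [WeeklyCounts-class] series covering the estimated weeks.
#' @param estimates data.frame from [farrington()] (columns `week_start`,
#'   `expected`, `lower`, `upper`; an `observed` column is used if the series
#'   does not cover a week).
#' @return data.frame with columns `week_start`, `observed`, `expected`,
#'   `lower`, `upper`, `flag`, `excess_low`, `excess_high`, `exiguous_low`,
#'   `exiguous_high`, `excess_pct_low`, `excess_pct_high`,
#'   `exiguous_pct_low`, `exiguous_pct_high`.
#' @export
excessTable <- function(series, estimates) {
  pos <- match(estimates$week_start, weekStarts(series))
  observed <- counts(series)[pos]
  if (anyNA(observed)) {
    if (!"observed" %in% names(estimates))
      stop("series does not cover estimated weeks ",
           paste(format(estimates$week_start[is.na(observed)]),
                 collapse = ", "))
    observed[is.na(observed)] <- estimates$observed[is.na(observed)]
  }
  rng <- excessRange(observed, estimates$expected, estimates$lower,
                     estimates$upper)
  out <- data.frame(
    week_start = estimates$week_start,
    observed = observed,
    expected = estimates$expected,
    lower = estimates$lower,
    upper = estimates$upper,
    flag = flagWeek(observed, estimates$lower, estimates$upper),
    rng
  )
  out$excess_pct_low <- excessPercentage(out$excess_low, out$expected)
  out$excess_pct_high <- excessPercentage(out$excess_high, out$expected)
  out$exiguous_pct_low <- excessPercentage(out$exiguous_low, out$expected)
  out$exiguous_pct_high <- excessPercentage(out$exiguous_high, out$expected)
  out
}

#' Cumulative excess/exiguous deaths over a period
#'
#' Endpoint-wise sums of the weekly ranges over `[from, to]`, plus the total
#' observed deaths. With `rule = "all_weeks"` (default) every week
#' contributes its `max(0, .)` values whether or not it is flagged; with
#' `"flagged_only"` only EXCESS weeks contribute to the excess range and
#' only EXIGUOUS weeks to the exiguous range.
#'
#' @param tbl a weekly excess table from [excessTable()].
#' @param from,to period bounds (dates; weeks by their Monday).
#' @param rule cumulation rule.
#' @return one-row data.frame: `observed`, `excess_low`, `excess_high`,
#'   `exiguous_low`, `exiguous_high`, `n_weeks`.
#' @export
cumulateExcess <- function(tbl, from = min(tbl$week_start),
                           to = max(tbl$week_start),
                           rule = c("all_weeks", "flagged_only")) {
  rule <- match.arg(rule)
  keep <- tbl$week_start >= weekOf(as.Date(from)) &
    tbl$week_start <= weekOf(as.Date(to))
  d <- tbl[keep, , drop = FALSE]
  ex <- if (rule == "flagged_only") d$flag == "EXCESS" else rep(TRUE, nrow(d))
  xg <- if (rule == "flagged_only") d$flag == "EXIGUOUS" else rep(TRUE, nrow(d))
  data.frame(
    observed = sum(d$observed),
    excess_low = sum(d$excess_low[ex]),
    excess_high = sum(d$excess_high[ex]),
    exiguous_low = sum(d$exiguous_low[xg]),
    exiguous_high = sum(d$exiguous_high[xg]),
    n_weeks = nrow(d)
  )
}

#' Maximal runs of consecutive excess weeks
#'
#' @param tbl a weekly excess table (gapless weeks).
#' @return data.frame with one row per maximal EXCESS run: `start` (first
#'   week's Monday), `end` (last week's Sunday), `n_weeks`.
#' @export
excessRuns <- function(tbl) {
  r <- rle(tbl$flag == "EXCESS")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start = tbl$week_start[starts[keep]],
    end = tbl$week_start[ends[keep]] + 6L,
    n_weeks = r$lengths[keep]
  )
}
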