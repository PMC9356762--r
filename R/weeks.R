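## Monday-start epidemiological weeks on a continuous axis.
## The week index counts Mondays from the epoch Monday 1970-01-05; all model
## trend covariates use this index (units: weeks).

.WEEK_EPOCH <- as.Date("1970-01-05")  # a Monday

#' Monday-start week containing a date
#'
#' Returns the Monday of the week containing `d` (the greatest Monday <= d).
#' Weeks span Monday through Sunday.
#'
#' @param d dates (coerced with [as.Date()]).
#' @return `Date` vector of Mondays.
#' @examples
#' weekOf("2021-05-05")  # the week of May 3-9, 2021
#' @export
weekOf <- function(d) {
  d <- as.Date(d)
  d - (as.integer(format(d, "%u")) - 1L)
}

#' Integer index of a week on the continuous weekly axis
#'
#' @param d dates or week-start Mondays.
#' @return integer index, step 1 per 7 days, increasing with the date.
#' @export
weekIndex <- function(d) {
  as.integer((as.integer(weekOf(d)) - as.integer(.WEEK_EPOCH)) %/% 7L)
}

#' Sequence of week-start Mondays covering a date range
#'
#' @param from,to dates; the axis runs from `weekOf(from)` to `weekOf(to)`.
#' @return `Date` vector of consecutive Mondays.
#' @export
weekSeq <- function(from, to) {
  seq(weekOf(as.Date(from)), weekOf(as.Date(to)), by = 7L)
}

#' Construct a WeeklyCounts series
#'
#' @param weekStart `Date` vector of consecutive Mondays (gapless).
#' @param counts nonnegative integer counts.
#' @param cause,place,region stratum labels.
#' @return a [WeeklyCounts-class] object.
#' @export
weeklyCounts <- function(weekStart, counts, cause = "NON_COVID_ALL",
                         place = "ALL", region = "JP") {
  new("WeeklyCounts", weekStart = as.Date(weekStart),
      counts = as.integer(counts), cause = cause, place = place,
      region = region)
}

#' Aggregate record-level deaths into stratified weekly count series
#'
#' Builds one gapless [WeeklyCounts-class] series per requested stratum over
#' the axis `weekOf(from) .. weekOf(to)`; weeks with no deaths carry 0.
#' Cause strata are built with [classifyCause()]; the `"NON_COVID_ALL"`
#' stratum uses [nonCovidAllCause()] (COVID-19 deaths excluded). `place =
#' "ALL"` and `region = "ALL"` are marginals over all values. Records dated
#' outside `[from, to]` are dropped with a message.
#'
#' @param records data.frame with columns `date`, `icd10`, `place`,
#'   `region`.
#' @param causes cause strata to build: cause categories and/or
#'   `"NON_COVID_ALL"`.
#' @param places place strata (subset of [PLACE_CATEGORIES]).
#' @param regions region strata (`"ALL"` = marginal).
#' @param from,to inclusive date range defining the weekly axis.
#' @return named list of [WeeklyCounts-class] objects (`"cause|place|region"`).
#' @export
aggregateRecords <- function(records,
                             causes = "NON_COVID_ALL",
                             places = "ALL",
                             regions = "ALL",
                             from, to) {
  stopifnot(all(c("date", "icd10", "place", "region") %in% names(records)))
  records$date <- as.Date(records$date)
  placeVocab <- setdiff(PLACE_CATEGORIES, "ALL")
  badPlace <- !(records$place %in% placeVocab)
  if (any(badPlace))
    stop("unknown place value(s) in records ",
         paste(utils::head(which(badPlace), 5L), collapse = ", "),
         ": ", paste(unique(records$place[badPlace]), collapse = ", "))
  if (anyNA(records$region) || any(!nzchar(records$region)))
    stop("missing region value(s) in records ",
         paste(utils::head(which(is.na(records$region) |
                                   !nzchar(records$region)), 5L),
               collapse = ", "))
  from <- as.Date(from); to <- as.Date(to)
  inRange <- records$date >= from & records$date <= to
  if (any(!inRange)) {
    message(sum(!inRange), " record(s) outside ", format(from), "..",
            format(to), " dropped")
    records <- records[inRange, , drop = FALSE]
  }
  axis <- weekSeq(from, to)
  wk <- weekIndex(records$date) - weekIndex(axis[1]) + 1L
  cat0 <- classifyCause(records$icd10)
  out <- list()
  for (cz in causes) {
    keepC <- if (cz == "NON_COVID_ALL") cat0 != "COVID19" else cat0 == cz
    for (pl in places) {
      keepP <- if (pl == "ALL") rep(TRUE, nrow(records))
               else records$place == pl
      for (rg in regions) {
        keepR <- if (rg == "ALL") rep(TRUE, nrow(records))
                 else records$region == rg
        idx <- wk[keepC & keepP & keepR]
        cnt <- tabulate(idx, nbins = length(axis))
        out[[paste(cz, pl, rg, sep = "|")]] <-
          weeklyCounts(axis, cnt, cause = cz, place = pl, region = rg)
      }
    }
  }
  out
}

## Delimited-text I/O ---------------------------------------------------------

#' Read record-level deaths from delimited text
#'
#' Expects a header `date,icd10,place,region` with ISO-8601 dates.
#'
#' @param path file path.
#' @return data.frame with parsed `Date` column.
#' @export
readDeathRecords <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "icd10", "place", "region") %in% names(rec)))
  rec$date <- as.Date(rec$date)
  rec
}

#' Read and write stratified weekly counts
#'
#' Long format with header `week_start,cause,place,region,deaths`.
#' `readWeeklyCounts()` returns a named list of [WeeklyCounts-class], one per
#' stratum present; `writeWeeklyCounts()` serializes such a list.
#'
#' @param path file path.
#' @return for `readWeeklyCounts()`, a named list of [WeeklyCounts-class].
#' @export
readWeeklyCounts <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("week_start", "cause", "place", "region", "deaths") %in%
                  names(tab)))
  tab$week_start <- as.Date(tab$week_start)
  key <- paste(tab$cause, tab$place, tab$region, sep = "|")
  lapply(split(tab, key), function(d) {
    d <- d[order(d$week_start), , drop = FALSE]
    weeklyCounts(d$week_start, d$deaths, cause = d$cause[1],
                 place = d$place[1], region = d$region[1])
  })
}

#' @param serieslist named list of [WeeklyCounts-class] objects.
#' @rdname readWeeklyCounts
#' @export
writeWeeklyCounts <- function(serieslist, path) {
  if (methods::is(serieslist, "WeeklyCounts")) serieslist <- list(serieslist)
  rows <- lapply(serieslist, function(s) {
    data.frame(week_start = format(weekStarts(s)), cause = s@cause,
               place = s@place, region = s@region, deaths = counts(s),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
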