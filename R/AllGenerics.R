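#' Accessors for weekly count series and related objects
#'
#' `weekStarts()` returns the Monday dates of the weekly axis, `counts()` the
#' observed counts, and `stratumLabel()` a `"cause|place|region"` identifier.
#'
#' @param object a [WeeklyCounts-class] or [ReportingTriangle-class] object.
#' @param ... unused.
#' @return `weekStarts()`: a `Date` vector; `counts()`: an integer vector or
#'   matrix; `stratumLabel()`: a character scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("weekStarts", function(object, ...) standardGeneric("weekStarts"))

#' @rdname accessors
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("stratumLabel",
           function(object, ...) standardGeneric("stratumLabel"))

#' @rdname accessors
#' @export
setMethod("weekStarts", "WeeklyCounts", function(object, ...) object@weekStart)

#' @rdname accessors
#' @export
setMethod("counts", "WeeklyCounts", function(object, ...) object@counts)

#' @rdname accessors
#' @export
setMethod("stratumLabel", "WeeklyCounts", function(object, ...) {
  paste(object@cause, object@place, object@region, sep = "|")
})

#' @rdname accessors
#' @export
setMethod("weekStarts", "ReportingTriangle",
          function(object, ...) object@weekStart)

#' @rdname accessors
#' @export
setMethod("counts", "ReportingTriangle", function(object, ...) object@counts)

#' @export
setMethod("length", "WeeklyCounts", function(x) length(x@weekStart))

setMethod("show", "WeeklyCounts", function(object) {
  n <- length(object)
  cat("WeeklyCounts:", stratumLabel(object), "\n")
  if (n) {
    cat(sprintf("  %d weeks: %s .. %s\n", n,
                format(object@weekStart[1]),
                format(object@weekStart[n] + 6)))
    cat(sprintf("  total deaths %d, weekly mean %.1f\n",
                sum(object@counts), mean(object@counts)))
  } else cat("  (empty)\n")
  invisible(object)
})

setMethod("show", "FarringtonConfig", function(object) {
  cat("FarringtonConfig\n")
  cat(sprintf("  b=%d years, w=%d weeks, %d+1 seasonal levels, level=%.2f\n",
              object@b, object@w, object@nSeason, object@level))
  cat(sprintf("  reweight threshold %.2f (%d pass), trend=%s, baseline=%s\n",
              object@reweightThreshold, object@maxReweightIter,
              object@trendMode, object@baselineMode))
  invisible(object)
})

setMethod("show", "FarringtonFit", function(object) {
  cat("FarringtonFit:", length(object@y), "design rows,",
      length(object@coefficients), "coefficients\n")
  cat(sprintf("  phi = %.3f, converged = %s\n", object@phi, object@converged))
  if (length(object@droppedColumns))
    cat("  dropped columns:", paste(object@droppedColumns, collapse = ", "),
        "\n")
  invisible(object)
})

setMethod("show", "ReportingTriangle", function(object) {
  cat(sprintf("ReportingTriangle: %d event weeks, delays 0..%d\n",
              nrow(object@counts), ncol(object@counts) - 1L))
  invisible(object)
})

setMethod("show", "MortalityScenario", function(object) {
  cat("MortalityScenario\n")
  cat(sprintf("  %d weeks from %s, %d strata, size=%s, seed=%d\n",
              object@nWeeks, format(object@startDate),
              nrow(object@strata),
              ifelse(is.finite(object@size),
                     format(object@size), "Inf (Poisson)"),
              object@seed))
  if (nrow(object@episodes))
    cat(sprintf("  %d episode(s), multipliers %s\n", nrow(object@episodes),
                paste(format(object@episodes$multiplier), collapse = ", ")))
  invisible(object)
})

#' Subset a weekly series to a window of weeks
#'
#' @param x a [WeeklyCounts-class] object.
#' @param from,to dates (coerced with [as.Date()]); weeks whose Monday lies
#'   in `[weekOf(from), weekOf(to)]` are retained.
#' @return a [WeeklyCounts-class] object.
#' @export
setGeneric("windowWeeks", function(x, from, to) standardGeneric("windowWeeks"))

#' @rdname windowWeeks
#' @export
setMethod("windowWeeks", "WeeklyCounts", function(x, from, to) {
  from <- weekOf(as.Date(from)); to <- weekOf(as.Date(to))
  keep <- x@weekStart >= from & x@weekStart <= to
  new("WeeklyCounts", weekStart = x@weekStart[keep],
      counts = x@counts[keep], cause = x@cause, place = x@place,
      region = x@region)
})
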