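#' @import methods
NULL

## Vocabulary shared across the package -------------------------------------

#' Cause-of-death categories
#'
#' The five analysis categories plus the categories needed to make the
#' classification a partition of all well-formed ICD-10 codes.
#' `NON_COVID_ALL` is a derived stratum label (all causes except COVID-19),
#' not a classification outcome.
#'
#' @export
CAUSE_CATEGORIES <- c("RESPIRATORY", "CIRCULATORY", "MALIGNANT_NEOPLASM",
                      "SENILITY", "COVID19", "OTHER")

#' Place-of-death categories
#'
#' Death-certificate location categories: hospitals and clinics, nursing
#' homes and elderly care facilities, home, and others. `ALL` denotes the
#' marginal (sum over the four specific places).
#'
#' @export
PLACE_CATEGORIES <- c("ALL", "HOSPITAL_CLINIC", "NURSING_ELDERLY", "HOME",
                      "OTHER")

## WeeklyCounts ---------------------------------------------------------------

#' WeeklyCounts: a gapless Monday-start weekly death count series
#'
#' One stratum's observed weekly death counts on a continuous axis of
#' Monday-start weeks. Weeks with no deaths carry an explicit zero.
#'
#' @slot weekStart `Date` vector of Mondays, gapless, strictly increasing by
#'   7 days.
#' @slot counts nonnegative integer counts, one per week.
#' @slot cause character scalar: a cause category or `"NON_COVID_ALL"`.
#' @slot place character scalar from [PLACE_CATEGORIES].
#' @slot region character scalar region code (e.g. `"JP"` for national).
#'
#' @export
setClass("WeeklyCounts",
  representation(
    weekStart = "Date",
    counts    = "integer",
    cause     = "character",
    place     = "character",
    region    = "character"
  )
)

setValidity("WeeklyCounts", function(object) {
  msg <- character()
  n <- length(object@weekStart)
  if (length(object@counts) != n)
    msg <- c(msg, "weekStart and counts must have equal length")
  if (n > 0) {
    wd <- as.integer(format(object@weekStart, "%u"))
    if (any(wd != 1L))
      msg <- c(msg, "all weekStart dates must be Mondays")
    if (n > 1 && any(diff(as.integer(object@weekStart)) != 7L))
      msg <- c(msg, "weekly axis must be gapless (consecutive Mondays)")
    if (anyNA(object@counts) || any(object@counts < 0L))
      msg <- c(msg, "counts must be nonnegative integers")
  }
  for (s in c("cause", "place", "region"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("%s must be a length-1 character", s))
  if (length(msg)) msg else TRUE
})

## FarringtonConfig -----------------------------------------------------------

#' FarringtonConfig: tuning parameters of the baseline model
#'
#' @slot b integer, years of history (default 5; 3 is used for the
#'   respiratory category where the longer history fits poorly).
#' @slot w integer, half-window in weeks around the target week's seasonal
#'   position (default 3).
#' @slot nSeason integer, number of equal off-season blocks in the seasonal
#'   factor (default 9; the reference window forms the 10th, baseline level).
#' @slot level two-sided prediction interval level (default 0.95).
#' @slot reweightThreshold positive Anscombe residual cutoff above which a
#'   historical week is downweighted (default 2.58).
#' @slot maxReweightIter integer, number of reweight-and-refit passes
#'   (default 1).
#' @slot trendMode `"ALWAYS"` (linear trend always retained — the modified
#'   algorithm) or `"ORIGINAL_CONDITIONAL"` (trend dropped when
#'   non-significant at 5%, fewer than 3 years of history, or the predicted
#'   value exceeds every historical observation).
#' @slot baselineMode `"FULL_HISTORY"` (all weeks in the b-year lookback,
#'   with the 9+1-level seasonal factor) or `"WINDOW_ONLY"` (only the
#'   reference-window weeks, no seasonal dummies).
#'
#' @export
setClass("FarringtonConfig",
  representation(
    b = "integer",
    w = "integer",
    nSeason = "integer",
    level = "numeric",
    reweightThreshold = "numeric",
    maxReweightIter = "integer",
    trendMode = "character",
    baselineMode = "character"
  ),
  prototype(
    b = 5L, w = 3L, nSeason = 9L, level = 0.95,
    reweightThreshold = 2.58, maxReweightIter = 1L,
    trendMode = "ALWAYS", baselineMode = "FULL_HISTORY"
  )
)

setValidity("FarringtonConfig", function(object) {
  msg <- character()
  if (object@b < 1L) msg <- c(msg, "b must be >= 1")
  if (object@w < 0L) msg <- c(msg, "w must be >= 0")
  if (object@nSeason < 1L) msg <- c(msg, "nSeason must be >= 1")
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must be in (0, 1)")
  if (object@reweightThreshold <= 0)
    msg <- c(msg, "reweightThreshold must be positive")
  if (!object@trendMode %in% c("ALWAYS", "ORIGINAL_CONDITIONAL"))
    msg <- c(msg, "trendMode must be ALWAYS or ORIGINAL_CONDITIONAL")
  if (!object@baselineMode %in% c("FULL_HISTORY", "WINDOW_ONLY"))
    msg <- c(msg, "baselineMode must be FULL_HISTORY or WINDOW_ONLY")
  if (2L * object@w + 1L >= 52L)
    msg <- c(msg, "reference window 2w+1 must be shorter than a year")
  if (object@baselineMode == "FULL_HISTORY" &&
      object@nSeason > 52L - (2L * object@w + 1L))
    msg <- c(msg, "more seasonal blocks than off-season weeks")
  if (length(msg)) msg else TRUE
})

## FarringtonFit --------------------------------------------------------------

#' FarringtonFit: one fitted quasi-Poisson baseline model
#'
#' The result of fitting the log-linear trend + seasonal-factor model to one
#' target week's historical design, after residual reweighting.
#'
#' @slot coefficients named numeric coefficient vector.
#' @slot covariance dispersion-scaled coefficient covariance matrix.
#' @slot phi dispersion estimate, floored at 1.
#' @slot fitted fitted means per design row (all positive).
#' @slot leverages hat values from the weighted fit.
#' @slot y observed counts per design row.
#' @slot weights prior weights used in the final fit (sum to n).
#' @slot X model matrix of the final fit.
#' @slot converged logical, IRLS convergence flag.
#' @slot droppedColumns names of design columns dropped for singularity.
#'
#' @export
setClass("FarringtonFit",
  representation(
    coefficients = "numeric",
    covariance = "matrix",
    phi = "numeric",
    fitted = "numeric",
    leverages = "numeric",
    y = "numeric",
    weights = "numeric",
    X = "matrix",
    converged = "logical",
    droppedColumns = "character"
  )
)

setValidity("FarringtonFit", function(object) {
  msg <- character()
  if (any(object@fitted <= 0)) msg <- c(msg, "fitted means must be positive")
  if (object@phi < 1) msg <- c(msg, "dispersion phi must be >= 1 (floored)")
  if (length(msg)) msg else TRUE
})

## ReportingTriangle ----------------------------------------------------------

#' ReportingTriangle: death counts by event week and reporting delay
#'
#' Row i, column d+1 holds the number of deaths occurring in event week i
#' that were reported d weeks later, for delays 0..D. `NA` marks cells not
#' yet observable (event week + delay beyond the data cut).
#'
#' @slot weekStart `Date` vector of event-week Mondays.
#' @slot counts numeric matrix, rows = event weeks, columns = delays 0..D.
#'
#' @export
setClass("ReportingTriangle",
  representation(weekStart = "Date", counts = "matrix")
)

setValidity("ReportingTriangle", function(object) {
  msg <- character()
  if (nrow(object@counts) != length(object@weekStart))
    msg <- c(msg, "one row per event week required")
  if (ncol(object@counts) < 1L)
    msg <- c(msg, "at least one delay column (delay 0) required")
  if (any(object@counts < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

## MortalityScenario ----------------------------------------------------------

#' MortalityScenario: parameters of the synthetic weekly mortality generator
#'
#' Defines, per stratum, a log-linear trend plus annual-sinusoid mean with
#' negative-binomial dispersion, multiplicative excess/exiguous episodes, and
#' a reporting-delay law. Defaults emulate the shape of Japanese vital
#' statistics used in national excess-mortality surveillance: ~9.5 years of
#' weekly counts starting Monday 2011-12-26, around 1000 deaths/week with a
#' slow upward trend and ~10% (log-scale) annual seasonality.
#'
#' @slot startDate `Date`, first week's Monday.
#' @slot nWeeks integer number of weeks.
#' @slot strata data.frame with columns cause, place, region, alpha
#'   (per-stratum baseline log mean).
#' @slot beta weekly log-scale trend slope.
#' @slot amplitude annual sinusoid amplitude on the log scale.
#' @slot phase annual sinusoid phase (radians).
#' @slot size negative-binomial size k (`Inf` = Poisson); local dispersion is
#'   phi = 1 + mu/k.
#' @slot episodes data.frame with columns start, end (1-based week
#'   positions, inclusive), multiplier (>= 0; > 1 excess, < 1 exiguous), and
#'   optionally stratum (label; `NA`/absent = all strata).
#' @slot delayLaw numeric probabilities over reporting delays 0..D, summing
#'   to 1.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("MortalityScenario",
  representation(
    startDate = "Date",
    nWeeks = "integer",
    strata = "data.frame",
    beta = "numeric",
    amplitude = "numeric",
    phase = "numeric",
    size = "numeric",
    episodes = "data.frame",
    delayLaw = "numeric",
    seed = "integer"
  )
)

setValidity("MortalityScenario", function(object) {
  msg <- character()
  if (as.integer(format(object@startDate, "%u")) != 1L)
    msg <- c(msg, "startDate must be a Monday")
  if (object@nWeeks < 1L) msg <- c(msg, "nWeeks must be >= 1")
  need <- c("cause", "place", "region", "alpha")
  if (!all(need %in% names(object@strata)))
    msg <- c(msg, "strata must have columns cause, place, region, alpha")
  if (object@size <= 0) msg <- c(msg, "size must be positive (Inf = Poisson)")
  if (nrow(object@episodes)) {
    if (!all(c("start", "end", "multiplier") %in% names(object@episodes)))
      msg <- c(msg, "episodes must have columns start, end, multiplier")
    else {
      if (any(object@episodes$multiplier < 0))
        msg <- c(msg, "episode multipliers must be >= 0")
      if (any(object@episodes$start > object@episodes$end))
        msg <- c(msg, "episode start must be <= end")
      if (any(object@episodes$start < 1L) ||
          any(object@episodes$end > object@nWeeks))
        msg <- c(msg, "episode windows must lie within the series")
    }
  }
  if (length(object@delayLaw) < 1L || any(object@delayLaw < 0) ||
      abs(sum(object@delayLaw) - 1) > 1e-8)
    msg <- c(msg, "delayLaw must be nonnegative and sum to 1")
  if (length(msg)) msg else TRUE
})
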