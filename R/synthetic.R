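## Synthetic weekly mortality generator.
##
## Counts are negative-binomial around a log-linear trend plus annual
## sinusoid (period 365.25/7 = 52.1775 weeks), with multiplicative
## excess/exiguous episodes. The sinusoidal seasonality is deliberately
## mismatched to the categorical seasonal factor used on the fitting side.

#' Construct a MortalityScenario
#'
#' Defaults emulate a national-scale surveillance dataset: 492 Monday-start
#' weeks from 2011-12-26 (covering 2012 through May 2021), one non-COVID
#' all-cause stratum at ~1000 deaths/week with a slow upward trend
#' (5e-4/week on the log scale), 10% log-scale annual seasonality, and
#' negative-binomial size 50. The default delay law puts most registrations
#' within 2 weeks and all within 13 weeks (~3 provisional months).
#'
#' @param startDate first week's Monday.
#' @param nWeeks number of weeks.
#' @param strata data.frame with columns cause, place, region, alpha
#'   (baseline log mean per stratum).
#' @param beta weekly log-scale trend slope.
#' @param amplitude,phase annual sinusoid amplitude (log scale) and phase.
#' @param size negative-binomial size k (`Inf` = Poisson).
#' @param episodes data.frame (start, end, multiplier[, stratum]); positions
#'   are 1-based week indices into the series.
#' @param delayLaw reporting-delay probabilities over delays 0..D.
#' @param seed RNG seed.
#' @return a [MortalityScenario-class].
#' @examples
#' mortalityScenario(nWeeks = 52, strata = data.frame(
#'   cause = "SENILITY", place = "HOME", region = "JP", alpha = log(20)))
#' @export
mortalityScenario <- function(startDate = as.Date("2011-12-26"),
                              nWeeks = 492,
                              strata = data.frame(
                                cause = "NON_COVID_ALL", place = "ALL",
                                region = "JP", alpha = log(1000),
                                stringsAsFactors = FALSE),
                              beta = 5e-4,
                              amplitude = 0.1,
                              phase = 0,
                              size = 50,
                              episodes = data.frame(start = integer(),
                                                    end = integer(),
                                                    multiplier = numeric()),
                              delayLaw = c(0.35, 0.30, 0.15, 0.08, 0.05,
                                           0.03, 0.015, 0.01, 0.005, 0.004,
                                           0.003, 0.002, 0.0005, 0.0005),
                              seed = 1L) {
  new("MortalityScenario", startDate = as.Date(startDate),
      nWeeks = as.integer(nWeeks), strata = strata, beta = beta,
      amplitude = amplitude, phase = phase, size = size,
      episodes = episodes, delayLaw = delayLaw / sum(delayLaw),
      seed = as.integer(seed))
}

.stratumLabels <- function(strata) {
  paste(strata$cause, strata$place, strata$region, sep = "|")
}

.scenarioMeans <- function(p) {
  t <- seq_len(p@nWeeks) - 1
  season <- p@amplitude * sin(2 * pi * t / 52.1775 + p@phase)
  labels <- .stratumLabels(p@strata)
  lapply(seq_len(nrow(p@strata)), function(i) {
    mu <- exp(p@strata$alpha[i] + p@beta * t + season)
    mult <- rep(1, p@nWeeks)
    if (nrow(p@episodes)) {
      ep <- p@episodes
      if ("stratum" %in% names(ep))
        ep <- ep[is.na(ep$stratum) | ep$stratum == labels[i], , drop = FALSE]
      for (j in seq_len(nrow(ep)))
        mult[ep$start[j]:ep$end[j]] <- ep$multiplier[j]
    }
    list(base = mu, mu = mu * mult, multiplier = mult)
  })
}

#' Simulate stratified weekly death-count series
#'
#' Counts are drawn negative-binomial with mean `mu_t x episode multiplier`
#' and size k (`Inf` gives Poisson), where
#' `mu_t = exp(alpha + beta t + A sin(2 pi t / 52.1775 + phase))`.
#' Identical scenario (including seed) gives identical output. The true
#' means and episode windows are attached as attribute `"truth"` per series.
#'
#' @param p a [MortalityScenario-class].
#' @return named list of [WeeklyCounts-class], one per stratum; each carries
#'   `attr(x, "truth") = list(mu, base, multiplier)`.
#' @export
simulateSeries <- function(p) {
  stopifnot(methods::is(p, "MortalityScenario"))
  set.seed(p@seed)
  means <- .scenarioMeans(p)
  axis <- p@startDate + 7L * (seq_len(p@nWeeks) - 1L)
  labels <- .stratumLabels(p@strata)
  out <- vector("list", nrow(p@strata))
  names(out) <- labels
  for (i in seq_len(nrow(p@strata))) {
    mu <- means[[i]]$mu
    y <- if (is.finite(p@size)) stats::rnbinom(p@nWeeks, mu = mu,
                                               size = p@size)
         else stats::rpois(p@nWeeks, mu)
    s <- weeklyCounts(axis, y, cause = p@strata$cause[i],
                      place = p@strata$place[i],
                      region = p@strata$region[i])
    attr(s, "truth") <- list(mu = mu, base = means[[i]]$base,
                             multiplier = means[[i]]$multiplier)
    out[[i]] <- s
  }
  out
}

#' Default ICD-10 code pools per cause category
#'
#' Representative underlying-cause codes used when emitting record-level
#' synthetic deaths; every pool classifies back into its category under
#' [classifyCause()] (the `NON_COVID_ALL` pool mixes non-COVID categories).
#'
#' @return named list of character vectors.
#' @export
defaultCodePools <- function() {
  list(
    RESPIRATORY = c("J12.9", "J18.9", "J44.9", "J45.9", "J96.0", "U04"),
    CIRCULATORY = c("I21.9", "I50.9", "I63.9", "I10", "I46.9"),
    MALIGNANT_NEOPLASM = c("C34.9", "C16.9", "C50.9", "C61"),
    SENILITY = c("R54"),
    COVID19 = c("U07.1"),
    OTHER = c("A41.9", "E14.9", "K70.3", "N18.9", "X59"),
    NON_COVID_ALL = c("J18.9", "I50.9", "C34.9", "R54", "A41.9", "E14.9")
  )
}

#' Simulate record-level deaths
#'
#' Draws the weekly counts with [simulateSeries()] (same seed, so the two
#' entry points agree exactly), then spreads each week's deaths uniformly
#' over its 7 days and assigns ICD-10 codes from the stratum's cause pool.
#' Re-aggregating the records reproduces the weekly counts exactly.
#'
#' @param p a [MortalityScenario-class].
#' @param codePools named list of ICD-10 codes per cause category.
#' @return data.frame with columns `date`, `icd10`, `place`, `region`.
#' @export
simulateRecords <- function(p, codePools = defaultCodePools()) {
  serieslist <- simulateSeries(p)
  rows <- list()
  for (i in seq_along(serieslist)) {
    s <- serieslist[[i]]
    pool <- codePools[[s@cause]]
    if (is.null(pool)) stop("no code pool for cause ", s@cause)
    n <- counts(s)
    tot <- sum(n)
    if (tot == 0L) next
    ws <- rep(weekStarts(s), n)
    rows[[i]] <- data.frame(
      date = ws + sample(0:6, tot, replace = TRUE),
      icd10 = sample(pool, tot, replace = TRUE),
      place = s@place, region = s@region,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Thin a weekly series by a reporting-delay law
#'
#' Each death is independently assigned a delay from `delayLaw`; counts
#' visible at `asOf` exclude reports landing after it. Returns the
#' provisional series (weeks up to `asOf`), the observable triangle (`NA`
#' beyond the cut), and the complete true triangle for round-trip tests.
#'
#' @param series a [WeeklyCounts-class] of final counts.
#' @param delayLaw probabilities over delays 0..D (sum to 1).
#' @param asOf data-cut week (date).
#' @return list with `provisional` ([WeeklyCounts-class]), `triangle`
#'   (observable [ReportingTriangle-class]), `trueTriangle` (complete).
#' @export
thinByDelay <- function(series, delayLaw, asOf) {
  stopifnot(abs(sum(delayLaw) - 1) < 1e-8, all(delayLaw >= 0))
  D <- length(delayLaw) - 1L
  n <- length(series)
  tri <- matrix(0, nrow = n, ncol = D + 1L)
  for (i in seq_len(n))
    tri[i, ] <- stats::rmultinom(1, counts(series)[i], delayLaw)
  ws <- weekStarts(series)
  asOfIdx <- weekIndex(as.Date(asOf))
  keep <- weekIndex(ws) <= asOfIdx
  obsTri <- tri
  for (d in 0:D)
    obsTri[weekIndex(ws) + d > asOfIdx, d + 1L] <- NA_real_
  visible <- rowSums(obsTri, na.rm = TRUE)[keep]
  list(
    provisional = weeklyCounts(ws[keep], visible, cause = series@cause,
                               place = series@place, region = series@region),
    triangle = reportingTriangle(ws[keep], obsTri[keep, , drop = FALSE]),
    trueTriangle = reportingTriangle(ws, tri)
  )
}
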