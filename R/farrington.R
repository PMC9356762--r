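## Modified Farrington baseline: per target week, a quasi-Poisson GLM
## log E(Y_t) = alpha + beta t + gamma_{f(t)} is fitted to historical weeks,
## past aberrations are downweighted via Anscombe residuals, and a two-sided
## prediction interval is computed on the 2/3-power scale.

#' Construct a FarringtonConfig
#'
#' @param b years of history (5 by default; 3 recommended for the
#'   respiratory category).
#' @param w half-window in weeks around the target seasonal position.
#' @param nSeason number of equal off-season blocks (the reference window is
#'   the additional baseline level).
#' @param level two-sided prediction interval level.
#' @param reweightThreshold Anscombe residual cutoff for downweighting.
#' @param maxReweightIter reweight-and-refit passes.
#' @param trendMode `"ALWAYS"` or `"ORIGINAL_CONDITIONAL"`.
#' @param baselineMode `"FULL_HISTORY"` or `"WINDOW_ONLY"`.
#' @return a [FarringtonConfig-class] object.
#' @examples
#' farringtonConfig()              # national defaults
#' farringtonConfig(b = 3)         # respiratory deaths
#' @export
farringtonConfig <- function(b = 5, w = 3, nSeason = 9, level = 0.95,
                             reweightThreshold = 2.58, maxReweightIter = 1,
                             trendMode = c("ALWAYS", "ORIGINAL_CONDITIONAL"),
                             baselineMode = c("FULL_HISTORY", "WINDOW_ONLY")) {
  new("FarringtonConfig", b = as.integer(b), w = as.integer(w),
      nSeason = as.integer(nSeason), level = level,
      reweightThreshold = reweightThreshold,
      maxReweightIter = as.integer(maxReweightIter),
      trendMode = match.arg(trendMode), baselineMode = match.arg(baselineMode))
}

#' Seasonal level of circular week offsets
#'
#' Offsets delta = (week index - target index) mod 52 within +/- w of the
#' target (circularly) form the reference level `"REF"`. The remaining
#' 52-(2w+1) offsets, traversed in increasing circular order starting at
#' w+1, are split into `nSeason` consecutive blocks of equal length (+/- 1
#' where the division leaves a remainder; earlier blocks take the extra
#' week). Week 53 of long years folds into offset 51's level via the mod-52
#' arithmetic.
#'
#' @param delta integer offsets in 0..51.
#' @param w half-window; `nSeason` number of off-season blocks.
#' @param nSeason number of off-season blocks.
#' @return character levels: `"REF"` or `"S1"`..`"S<nSeason>"`.
#' @keywords internal
seasonLevelOf <- function(delta, w, nSeason) {
  stopifnot(all(delta >= 0 & delta < 52))
  circ <- pmin(delta, 52L - delta)
  lev <- rep("REF", length(delta))
  off <- circ > w
  m <- 52L - (2L * w + 1L)           # number of off-season offsets
  q <- m %/% nSeason; r <- m %% nSeason
  sizes <- rep(q, nSeason) + c(rep(1L, r), rep(0L, nSeason - r))
  upper <- cumsum(sizes)             # block boundaries in 0-based position
  pos <- delta[off] - (w + 1L)       # 0 .. m-1 in increasing circular order
  lev[off] <- paste0("S", findInterval(pos, upper) + 1L)
  lev
}

#' Build the historical design for one target week
#'
#' With `baselineMode = "FULL_HISTORY"`, one row per week from
#' `target - 52 b` weeks through `target - 1` week (the target week itself is
#' never included), each labelled with its seasonal level. With
#' `"WINDOW_ONLY"`, only the reference-window rows (circular offset within
#' +/- w) are kept and no seasonal dummies are produced.
#'
#' @param series a [WeeklyCounts-class] covering at least `b` years before
#'   `target`.
#' @param target target week (date; its Monday-start week is used).
#' @param cfg a [FarringtonConfig-class].
#' @return data.frame with columns `weekStart`, `t` (week index),
#'   `y`, `seasonLevel`, `weight` (1).
#' @export
buildReferenceDesign <- function(series, target, cfg = farringtonConfig()) {
  target <- weekOf(as.Date(target))
  it <- weekIndex(target)
  i0 <- weekIndex(weekStarts(series)[1])
  iN <- i0 + length(series) - 1L
  lo <- it - 52L * cfg@b
  if (lo < i0)
    stop(sprintf(
      "insufficient history for %s: need weeks back to %s (b=%d years), series starts %s",
      format(target), format(.WEEK_EPOCH + 7L * lo), cfg@b,
      format(weekStarts(series)[1])))
  if (it - 1L > iN)
    stop(sprintf("series ends %s, before the week preceding target %s",
                 format(weekStarts(series)[length(series)]), format(target)))
  idx <- lo:(it - 1L)
  y <- counts(series)[idx - i0 + 1L]
  delta <- (idx - it) %% 52L
  lev <- seasonLevelOf(delta, cfg@w, cfg@nSeason)
  d <- data.frame(
    weekStart = .WEEK_EPOCH + 7L * idx,
    t = idx, y = y, seasonLevel = lev, weight = 1,
    stringsAsFactors = FALSE
  )
  if (cfg@baselineMode == "WINDOW_ONLY") {
    d <- d[d$seasonLevel == "REF", , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

## Model matrix: intercept + trend + off-season dummies (REF is baseline).
.designMatrix <- function(design, trend = TRUE) {
  X <- cbind(`(Intercept)` = rep(1, nrow(design)))
  if (trend) X <- cbind(X, t = design$t)
  levs <- sort(unique(design$seasonLevel))
  for (lv in setdiff(levs, "REF"))
    X <- cbind(X, as.numeric(design$seasonLevel == lv))
  colnames(X) <- c(colnames(X)[seq_len(1 + trend)], setdiff(levs, "REF"))
  X
}

#' Fit the weighted quasi-Poisson model
#'
#' IRLS fit (via [stats::glm.fit()], log link, relative tolerance 1e-9, at
#' most 100 iterations) of the Poisson log-likelihood with per-row prior
#' weights. The dispersion is the weighted Pearson chi-square over residual
#' degrees of freedom, floored at 1 to avoid anti-conservative intervals;
#' the coefficient covariance is the dispersion-scaled inverse Fisher
#' information. Design columns that are empty or aliased (e.g. a seasonal
#' level with no data) are dropped with a warning.
#'
#' @param X model matrix (rows = historical weeks).
#' @param y observed counts.
#' @param weights prior weights (default 1).
#' @return a [FarringtonFit-class] object.
#' @export
fitQuasiPoisson <- function(X, y, weights = rep(1, length(y))) {
  stopifnot(nrow(X) == length(y), length(weights) == length(y))
  dropped <- character()
  empty <- colSums(abs(X)) == 0
  if (any(empty)) {
    dropped <- colnames(X)[empty]
    warning("dropping empty design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !empty, drop = FALSE]
  }
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, weights = weights,
    family = stats::quasipoisson(link = "log"),
    control = stats::glm.control(epsilon = 1e-9, maxit = 100L)
  ))
  if (anyNA(fit$coefficients)) {
    alias <- names(fit$coefficients)[is.na(fit$coefficients)]
    warning("dropping aliased design column(s): ",
            paste(alias, collapse = ", "))
    dropped <- c(dropped, alias)
    X <- X[, setdiff(colnames(X), alias), drop = FALSE]
    fit <- suppressWarnings(stats::glm.fit(
      x = X, y = y, weights = weights,
      family = stats::quasipoisson(link = "log"),
      control = stats::glm.control(epsilon = 1e-9, maxit = 100L)
    ))
  }
  if (!fit$converged)
    warning("IRLS did not converge in 100 iterations; using last iterate")
  mu <- fit$fitted.values
  n <- length(y); p <- fit$rank
  pearson <- sum(weights * (y - mu)^2 / mu)
  phi <- max(1, pearson / (n - p))
  W <- weights * mu                       # IRLS weights, log link
  A <- crossprod(X * sqrt(W))             # Fisher information
  covUnscaled <- solve(A)
  h <- rowSums((X %*% covUnscaled) * X) * W
  new("FarringtonFit",
      coefficients = fit$coefficients,
      covariance = phi * covUnscaled,
      phi = phi, fitted = mu, leverages = h, y = as.numeric(y),
      weights = weights, X = X, converged = fit$converged,
      droppedColumns = dropped)
}

#' Anscombe residuals of a fitted baseline
#'
#' Variance-stabilized residuals
#' \deqn{r_i = \frac{3}{2}\,\frac{y_i^{2/3} - \hat\mu_i^{2/3}}
#'   {\hat\phi^{1/2}\,\hat\mu_i^{1/6}\,(1 - h_i)^{1/2}}}
#' with leverages \eqn{h_i} from the weighted fit; used to detect and
#' downweight past aberrant weeks.
#'
#' @param fit a [FarringtonFit-class].
#' @return numeric residual vector.
#' @export
anscombeResiduals <- function(fit) {
  mu <- fit@fitted
  if (any(mu <= 0)) stop("fitted means must be positive")
  h <- pmin(fit@leverages, 1 - 1e-10)
  1.5 * (fit@y^(2 / 3) - mu^(2 / 3)) /
    (sqrt(fit@phi) * mu^(1 / 6) * sqrt(1 - h))
}

#' Fit with downweighting of past aberrations
#'
#' Fits the model, computes Anscombe residuals, and — if any residual
#' exceeds `reweightThreshold` — refits with weights \eqn{w_i = k r_i^{-2}}
#' for exceeding rows and \eqn{w_i = k} otherwise, `k` normalizing the
#' weights to sum to n. Repeated up to `maxReweightIter` times; if no
#' residual exceeds the threshold the current fit is returned unchanged.
#'
#' @param X model matrix; `y` observed counts.
#' @param y observed counts.
#' @param cfg a [FarringtonConfig-class].
#' @return a [FarringtonFit-class].
#' @export
reweightAndRefit <- function(X, y, cfg = farringtonConfig()) {
  fit <- fitQuasiPoisson(X, y)
  n <- length(y)
  for (iter in seq_len(cfg@maxReweightIter)) {
    r <- anscombeResiduals(fit)
    exceed <- r > cfg@reweightThreshold
    if (!any(exceed)) break
    gamma <- ifelse(exceed, r^-2, 1)
    w <- gamma * n / sum(gamma)
    fit <- fitQuasiPoisson(X, y, weights = w)
  }
  fit
}

#' Prediction for the target week with two-sided bounds
#'
#' The expected count is \eqn{\hat\mu_0 = \exp(x_0'\hat\theta)} with
#' \eqn{x_0} the target covariates (intercept, trend at the target week
#' index, reference seasonal level). Its variance is
#' \eqn{\hat\mu_0^2\, x_0'\hat\Sigma x_0}. Prediction bounds are computed on
#' the 2/3-power scale:
#' \deqn{U/L = \hat\mu_0\Big(1 \pm z_{1-\alpha/2}\,\tfrac{2}{3}\,
#'   \sqrt{\hat\phi\hat\mu_0 + \widehat{Var}(\hat\mu_0)}/\hat\mu_0\Big)^{3/2}}
#' with the inner factor floored at 0 before the 3/2 power, so the lower
#' bound is never negative.
#'
#' @param fit a [FarringtonFit-class].
#' @param target target week (date).
#' @param cfg a [FarringtonConfig-class] (supplies the interval level).
#' @return one-row data.frame: `week_start`, `expected`, `var_mu`, `phi`,
#'   `lower`, `upper`.
#' @export
predictWeek <- function(fit, target, cfg = farringtonConfig()) {
  target <- weekOf(as.Date(target))
  cn <- colnames(fit@X)
  x0 <- numeric(length(cn)); names(x0) <- cn
  x0["(Intercept)"] <- 1
  if ("t" %in% cn) x0["t"] <- weekIndex(target)
  # target week is at the reference seasonal level: all dummies zero
  mu0 <- exp(sum(x0 * fit@coefficients[cn]))
  varMu <- as.numeric(mu0^2 * (x0 %*% fit@covariance %*% x0))
  z <- stats::qnorm(1 - (1 - cfg@level) / 2)
  half <- z * (2 / 3) * sqrt(fit@phi * mu0 + varMu) / mu0
  upper <- mu0 * (1 + half)^1.5
  lower <- mu0 * max(0, 1 - half)^1.5
  data.frame(week_start = target, expected = mu0, var_mu = varMu,
             phi = fit@phi, lower = lower, upper = upper)
}

## Original-algorithm trend rule: keep the trend only when it is significant
## at 5%, at least 3 years of history are available, and the prediction does
## not exceed every historical observation.
.dropTrend <- function(fit, target, cfg) {
  if (!"t" %in% colnames(fit@X)) return(FALSE)
  if (cfg@b < 3L) return(TRUE)
  se <- sqrt(fit@covariance["t", "t"])
  pval <- 2 * stats::pnorm(-abs(fit@coefficients["t"] / se))
  if (pval > 0.05) return(TRUE)
  mu0 <- predictWeek(fit, target, cfg)$expected
  mu0 > max(fit@y)
}

#' Baseline estimate and prediction bounds for target weeks
#'
#' Runs the full modified Farrington procedure for each target week: build
#' the historical design, fit the weighted quasi-Poisson model with
#' downweighting of past aberrations, apply the trend rule, and compute the
#' two-sided prediction interval. `farringtonWeek()` handles a single week;
#' `farrington()` maps over an ordered set of target weeks, refitting per
#' week.
#'
#' @param series a [WeeklyCounts-class] series.
#' @param target one target week (`farringtonWeek`) or a vector of target
#'   dates (`farrington`).
#' @param cfg a [FarringtonConfig-class].
#' @return data.frame with one row per target week: `week_start`,
#'   `expected`, `var_mu`, `phi`, `lower`, `upper`, `observed` (NA if the
#'   series does not cover the week), `converged`, `trend_kept`, `n_rows`.
#' @examples
#' sc <- mortalityScenario(nWeeks = 364, seed = 7)
#' s <- simulateSeries(sc)[[1]]
#' farringtonWeek(s, weekStarts(s)[320], farringtonConfig())
#' @export
farringtonWeek <- function(series, target, cfg = farringtonConfig()) {
  target <- weekOf(as.Date(target))
  design <- buildReferenceDesign(series, target, cfg)
  X <- .designMatrix(design, trend = TRUE)
  fit <- reweightAndRefit(X, design$y, cfg)
  trendKept <- TRUE
  if (cfg@trendMode == "ORIGINAL_CONDITIONAL" &&
      .dropTrend(fit, target, cfg)) {
    X <- .designMatrix(design, trend = FALSE)
    fit <- reweightAndRefit(X, design$y, cfg)
    trendKept <- FALSE
  }
  est <- predictWeek(fit, target, cfg)
  ws <- weekStarts(series)
  pos <- match(target, ws)
  est$observed <- if (is.na(pos)) NA_integer_ else counts(series)[pos]
  est$converged <- fit@converged
  est$trend_kept <- trendKept
  est$n_rows <- nrow(design)
  est
}

#' @param targets vector of target dates for `farrington()`.
#' @rdname farringtonWeek
#' @export
farrington <- function(series, targets, cfg = farringtonConfig()) {
  rows <- lapply(as.Date(targets), farringtonWeek, series = series, cfg = cfg)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
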