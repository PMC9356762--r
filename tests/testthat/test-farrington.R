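test_that("seasonal levels partition the year into a reference window plus equal blocks", {
  delta <- 0:51
  lev <- exmort:::seasonLevelOf(delta, w = 3L, nSeason = 9L)
  expect_equal(sum(lev == "REF"), 7)            # offsets 0..3 and 49..51
  expect_equal(as.vector(table(lev[lev != "REF"])), rep(5L, 9))
  # blocks are consecutive in circular order starting at w+1
  expect_equal(lev[delta %in% 4:8], rep("S1", 5))
  expect_equal(lev[delta %in% 44:48], rep("S9", 5))
  expect_equal(lev[delta %in% c(49, 51)], c("REF", "REF"))
})

test_that("degenerate window w=0 with one off-season block gives two levels", {
  lev <- exmort:::seasonLevelOf(0:51, w = 0L, nSeason = 1L)
  expect_equal(sum(lev == "REF"), 1)
  expect_equal(sum(lev == "S1"), 51)
})

test_that("full-history design covers exactly 52b weeks before the target", {
  s <- nullSeries(5)
  target <- weekStarts(s)[313]
  d <- buildReferenceDesign(s, target, farringtonConfig(b = 5))
  expect_equal(nrow(d), 260)
  expect_true(all(d$weekStart < target))        # target week never included
  expect_equal(max(d$weekStart), target - 7)
  expect_equal(min(d$weekStart), target - 7 * 260)
  expect_equal(sum(d$seasonLevel == "REF"), 5 * 7)
  # window-only mode keeps just the reference offsets, no seasonal dummies
  dw <- buildReferenceDesign(s, target,
                             farringtonConfig(b = 5,
                                              baselineMode = "WINDOW_ONLY"))
  expect_equal(nrow(dw), 35)
  expect_true(all(dw$seasonLevel == "REF"))
})

test_that("insufficient history is reported with the required span", {
  s <- nullSeries(5, nWeeks = 200)
  expect_error(
    buildReferenceDesign(s, weekStarts(s)[150], farringtonConfig(b = 5)),
    "insufficient history")
})

test_that("intercept-only quasi-Poisson fit recovers the sample mean", {
  y <- c(10, 12, 8, 10)
  fit <- fitQuasiPoisson(matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)")),
                         y)
  expect_equal(unname(exp(fit@coefficients)), mean(y), tolerance = 1e-8)
})

test_that("dispersion is near 1 for equidispersed counts and floored at 1", {
  set.seed(31)
  n <- 260
  y <- rpois(n, 100)
  X <- cbind(`(Intercept)` = 1, t = scale(seq_len(n))[, 1])
  fit <- fitQuasiPoisson(X, y)
  mu <- fit@fitted
  rawPhi <- sum((y - mu)^2 / mu) / (n - 2)
  expect_gt(rawPhi, 0.8)
  expect_lt(rawPhi, 1.2)
  expect_gte(fit@phi, 1)
})

test_that("IRLS coefficients match a generic-optimizer likelihood maximum", {
  set.seed(32)
  for (rep in 1:5) {
    n <- 30
    X <- cbind(`(Intercept)` = 1,
               t = scale(seq_len(n))[, 1],
               S1 = as.numeric(seq_len(n) %% 3 == 0))
    mu <- exp(3 + 0.2 * X[, 2] - 0.3 * X[, 3])
    y <- rpois(n, mu)
    w <- runif(n, 0.5, 1.5)
    fit <- fitQuasiPoisson(X, y, weights = w)
    oracle <- optimPoissonFit(X, y, weights = w)
    expect_equal(unname(fit@coefficients), unname(oracle), tolerance = 1e-6)
  }
})

test_that("Anscombe residuals follow the variance-stabilized formula", {
  set.seed(33)
  n <- 20
  X <- cbind(`(Intercept)` = 1, t = scale(seq_len(n))[, 1])
  y <- rpois(n, 50)
  fit <- fitQuasiPoisson(X, y)
  r <- anscombeResiduals(fit)
  # direct evaluation, written out independently of the package routine
  direct <- (3 / 2) * (y^(2 / 3) - fit@fitted^(2 / 3)) /
    (fit@phi^0.5 * fit@fitted^(1 / 6) * (1 - fit@leverages)^0.5)
  expect_equal(r, direct, tolerance = 1e-12)
  # zero at y = mu
  fitc <- fitQuasiPoisson(matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)")),
                          rep(10, 4))
  expect_equal(anscombeResiduals(fitc), rep(0, 4), tolerance = 1e-9)
  # sign-monotone in y at fixed mu: constant-mean fit orders residuals as y
  set.seed(331)
  y3 <- rpois(30, 25)
  fit3 <- fitQuasiPoisson(matrix(1, 30, 1,
                                 dimnames = list(NULL, "(Intercept)")), y3)
  r3 <- anscombeResiduals(fit3)
  expect_equal(order(r3), order(y3))
  expect_true(all(sign(r) == sign(y - fit@fitted) | y == fit@fitted))
})

test_that("reweighting downweights aberrant weeks and renormalizes", {
  set.seed(34)
  n <- 60
  X <- cbind(`(Intercept)` = rep(1, n))
  y <- rpois(n, 20)
  # no exceedance: the fit is returned unchanged
  cfgHi <- farringtonConfig(reweightThreshold = 1e6)
  fit0 <- reweightAndRefit(X, y, cfgHi)
  expect_equal(fit0@weights, rep(1, n))
  # one gross outlier: weight < 1, refit expectation decreases
  y2 <- y; y2[10] <- 10 * round(mean(y))
  base <- fitQuasiPoisson(X, y2)
  re <- reweightAndRefit(X, y2, farringtonConfig())
  expect_lt(re@weights[10], 1)
  expect_lt(exp(re@coefficients[1]), exp(base@coefficients[1]))
  expect_equal(sum(re@weights), n, tolerance = 1e-9)
})

test_that("prediction bounds approximate Poisson quantiles when phi=1, var=0", {
  mkfit <- function(mu) new("FarringtonFit",
    coefficients = c(`(Intercept)` = log(mu)),
    covariance = matrix(0, 1, 1, dimnames = list("(Intercept)",
                                                 "(Intercept)")),
    phi = 1, fitted = rep(mu, 4), leverages = rep(0, 4), y = rep(mu, 4),
    weights = rep(1, 4),
    X = matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)")),
    converged = TRUE, droppedColumns = character())
  est <- predictWeek(mkfit(100), as.Date("2021-05-03"))
  expect_equal(est$expected, 100)
  expect_equal(est$upper, 120.2, tolerance = 1e-3)
  # oracle: 97.5% quantile by cumulative pmf summation
  cdf <- cumsum(dpois(0:200, 100))
  q975 <- min(which(cdf >= 0.975)) - 1
  expect_lt(abs(est$upper - q975), 1)
})

test_that("intervals widen monotonically with dispersion and stay nonnegative", {
  mkfit <- function(mu, phi) new("FarringtonFit",
    coefficients = c(`(Intercept)` = log(mu)),
    covariance = matrix(0, 1, 1, dimnames = list("(Intercept)",
                                                 "(Intercept)")),
    phi = phi, fitted = rep(mu, 4), leverages = rep(0, 4), y = rep(mu, 4),
    weights = rep(1, 4),
    X = matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)")),
    converged = TRUE, droppedColumns = character())
  ups <- sapply(c(1, 2, 5, 20, 100),
                function(p) predictWeek(mkfit(100, p),
                                        as.Date("2021-05-03"))$upper)
  expect_true(all(diff(ups) > 0))
  lo <- predictWeek(mkfit(0.5, 50), as.Date("2021-05-03"))
  expect_gte(lo$lower, 0)
  expect_lte(lo$lower, lo$expected)
  expect_lte(lo$expected, lo$upper)
})

test_that("estimates are invariant to shifting the calendar origin", {
  s <- nullSeries(6)
  shift <- 35L * 7L  # shift the whole series by 35 weeks
  s2 <- weeklyCounts(weekStarts(s) + shift, counts(s))
  t1 <- weekStarts(s)[320]
  e1 <- farringtonWeek(s, t1)
  e2 <- farringtonWeek(s2, t1 + shift)
  for (col in c("expected", "var_mu", "phi", "lower", "upper"))
    expect_equal(e1[[col]], e2[[col]], tolerance = 1e-8)
})

test_that("scaling all counts by k scales the expectation by about k", {
  s <- nullSeries(7)
  k <- 3L
  s2 <- weeklyCounts(weekStarts(s), counts(s) * k)
  t1 <- weekStarts(s)[320]
  e1 <- farringtonWeek(s, t1)
  e2 <- farringtonWeek(s2, t1)
  expect_equal(e2$expected / e1$expected, k, tolerance = 0.02)
})

test_that("the original conditional trend rule drops a flat trend", {
  # flat series: trend non-significant, conditional mode drops it
  set.seed(35)
  axis <- seq(weekOf("2012-01-02"), by = 7, length.out = 320)
  s <- weeklyCounts(axis, rpois(320, 40))
  target <- axis[315]
  eAlways <- farringtonWeek(s, target, farringtonConfig(trendMode = "ALWAYS"))
  eCond <- farringtonWeek(s, target,
                          farringtonConfig(trendMode = "ORIGINAL_CONDITIONAL"))
  expect_true(eAlways$trend_kept)
  expect_false(eCond$trend_kept)
  # and keeps a strong trend
  s2 <- simulateSeries(mortalityScenario(nWeeks = 320, beta = 0.002,
                                         amplitude = 0, seed = 36))[[1]]
  eCond2 <- farringtonWeek(s2, weekStarts(s2)[315],
                           farringtonConfig(trendMode = "ORIGINAL_CONDITIONAL"))
  expect_true(eCond2$trend_kept)
})
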