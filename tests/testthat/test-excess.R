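test_that("weeks are flagged by strict bound exceedance", {
  expect_equal(flagWeek(120, 90, 110), "EXCESS")
  expect_equal(flagWeek(110, 90, 110), "NONE")   # boundary is not excess
  expect_equal(flagWeek(40, 50, 110), "EXIGUOUS")
  expect_equal(flagWeek(50, 50, 110), "NONE")
  expect_equal(flagWeek(c(120, 40, 100), c(50, 50, 50), c(110, 110, 110)),
               c("EXCESS", "EXIGUOUS", "NONE"))
})

test_that("excess and exiguous ranges run from the bound gap to the mean gap", {
  r <- excessRange(120, 100, 90, 110)
  expect_equal(c(r$excess_low, r$excess_high), c(10, 20))
  # unflagged week still contributes to the high endpoint
  r2 <- excessRange(105, 100, 90, 110)
  expect_equal(c(r2$excess_low, r2$excess_high), c(0, 5))
  r3 <- excessRange(100, 100, 90, 110)
  expect_equal(unlist(r3), c(excess_low = 0, excess_high = 0,
                             exiguous_low = 0, exiguous_high = 0))
  # mirror-image deficit
  r4 <- excessRange(40, 100, 50, 150)
  expect_equal(c(r4$exiguous_low, r4$exiguous_high), c(10, 60))
  # low <= high always, entries nonnegative
  set.seed(41)
  obs <- rpois(100, 100)
  ex <- excessRange(obs, 100, 80, 120)
  expect_true(all(ex$excess_low <= ex$excess_high))
  expect_true(all(ex$exiguous_low <= ex$exiguous_high))
  expect_true(all(unlist(ex) >= 0))
})

test_that("excess percentage is deaths over expected, in percent", {
  expect_equal(excessPercentage(c(50, 100), 1000), c(5, 10))
  expect_equal(excessPercentage(c(0, 0), 123), c(0, 0))
  expect_error(excessPercentage(c(1, 2), 0), "positive")
  # a printed national range and its percentage must share one expected value
  pct <- excessPercentage(c(689, 2161), 2161 / 0.0858)
  expect_equal(pct[2], 8.58, tolerance = 1e-10)
  expect_lt(abs(pct[1] - 2.73), 0.01)
})

test_that("cumulative ranges are endpoint-wise sums over the period", {
  tbl <- excessTable(
    weeklyCounts(weekSeq("2021-04-05", "2021-04-18"), c(120, 105)),
    estRows(c("2021-04-05", "2021-04-12"), expected = c(100, 100),
            lower = c(90, 90), upper = c(110, 110)))
  cum <- cumulateExcess(tbl)
  expect_equal(c(cum$excess_low, cum$excess_high), c(10, 25))
  expect_equal(cum$observed, 225)
  # all-zero ranges cumulate to zero
  tbl0 <- excessTable(
    weeklyCounts(weekSeq("2021-04-05", "2021-04-18"), c(100, 100)),
    estRows(c("2021-04-05", "2021-04-12"), expected = c(100, 100),
            lower = c(90, 90), upper = c(110, 110)))
  cum0 <- cumulateExcess(tbl0)
  expect_equal(c(cum0$excess_low, cum0$excess_high,
                 cum0$exiguous_low, cum0$exiguous_high), rep(0, 4))
})

test_that("cumulation matches a week-by-week loop on a synthetic scenario", {
  sc <- mortalityScenario(
    nWeeks = 320, size = Inf,
    episodes = data.frame(start = 310L, end = 313L, multiplier = 1.3),
    seed = 42)
  s <- simulateSeries(sc)[[1]]
  targets <- weekStarts(s)[305:318]
  tbl <- excessTable(s, farrington(s, targets))
  cum <- cumulateExcess(tbl)
  # brute-force loop oracle
  lo <- hi <- xlo <- xhi <- 0
  for (i in seq_len(nrow(tbl))) {
    lo <- lo + max(0, tbl$observed[i] - tbl$upper[i])
    hi <- hi + max(0, tbl$observed[i] - tbl$expected[i])
    xlo <- xlo + max(0, tbl$lower[i] - tbl$observed[i])
    xhi <- xhi + max(0, tbl$expected[i] - tbl$observed[i])
  }
  expect_equal(cum$excess_low, lo)
  expect_equal(cum$excess_high, hi)
  expect_equal(cum$exiguous_low, xlo)
  expect_equal(cum$exiguous_high, xhi)
  # additive over disjoint periods
  a <- cumulateExcess(tbl, targets[1], targets[7])
  b <- cumulateExcess(tbl, targets[8], targets[14])
  expect_equal(a$excess_high + b$excess_high, cum$excess_high)
  expect_equal(a$observed + b$observed, cum$observed)
  # flagged-only variant never exceeds the all-weeks rule
  cf <- cumulateExcess(tbl, rule = "flagged_only")
  expect_lte(cf$excess_high, cum$excess_high)
})

test_that("a week is never both excess and exiguous, and percentages are scale-free", {
  set.seed(43)
  obs <- rpois(50, 100)
  fl <- flagWeek(obs, 85, 115)
  expect_true(all(fl %in% c("EXCESS", "EXIGUOUS", "NONE")))
  k <- 7
  r1 <- excessRange(obs, 100, 85, 115)
  rk <- excessRange(obs * k, 100 * k, 85 * k, 115 * k)
  expect_equal(100 * rk$excess_high / (100 * k),
               100 * r1$excess_high / 100)
})

test_that("maximal excess runs are reported with calendar endpoints", {
  mk <- function(flags) {
    n <- length(flags)
    obs <- ifelse(flags == "E", 200, ifelse(flags == "X", 10, 100))
    excessTable(
      weeklyCounts(seq(weekOf("2021-04-05"), by = 7, length.out = n), obs),
      estRows(seq(weekOf("2021-04-05"), by = 7, length.out = n),
              expected = rep(100, n), lower = rep(50, n),
              upper = rep(150, n)))
  }
  r <- excessRuns(mk(c("N", "E", "E", "N")))
  expect_equal(nrow(r), 1)
  expect_equal(r$n_weeks, 2)
  expect_equal(r$start, as.Date("2021-04-12"))
  expect_equal(r$end, as.Date("2021-04-25"))    # Sunday of the last week
  expect_equal(nrow(excessRuns(mk(c("N", "N", "X")))), 0)
  r2 <- excessRuns(mk(c("E", "N", "E")))
  expect_equal(nrow(r2), 2)
  expect_equal(r2$n_weeks, c(1, 1))
})
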