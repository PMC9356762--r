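# Shared fixtures, built in code.

# A small multi-stratum scenario: two causes x two places, modest counts.
smallScenario <- function(seed = 101, nWeeks = 30) {
  mortalityScenario(
    startDate = as.Date("2019-01-07"), nWeeks = nWeeks,
    strata = data.frame(
      cause = c("CIRCULATORY", "CIRCULATORY", "SENILITY", "SENILITY"),
      place = c("HOSPITAL_CLINIC", "HOME", "HOSPITAL_CLINIC", "HOME"),
      region = "R01",
      alpha = log(c(30, 12, 8, 15)),
      stringsAsFactors = FALSE
    ),
    beta = 0, amplitude = 0, size = Inf, seed = seed
  )
}

# Null national-style series long enough to fit b = 5 with a year to score.
nullSeries <- function(seed, nWeeks = 364) {
  simulateSeries(mortalityScenario(nWeeks = nWeeks, seed = seed))[[1]]
}

# Hand-built weekly estimate rows for excess arithmetic tests.
estRows <- function(week_start, expected, lower, upper, observed = NULL) {
  d <- data.frame(week_start = as.Date(week_start), expected = expected,
                  var_mu = 0, phi = 1, lower = lower, upper = upper)
  if (!is.null(observed)) d$observed <- observed
  d
}

# Independent weighted Poisson log-likelihood maximizer (generic optimizer),
# used as the oracle against the IRLS fit.
optimPoissonFit <- function(X, y, weights = rep(1, length(y))) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(weights * (y * eta - exp(eta)))
  }
  grad <- function(beta) {
    mu <- exp(drop(X %*% beta))
    -drop(crossprod(X, weights * (y - mu)))
  }
  start <- c(log(max(mean(y), 0.1)), rep(0, ncol(X) - 1))
  o <- stats::optim(start, nll, grad, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  # polish with a second pass from the BFGS solution
  o <- stats::optim(o$par, nll, grad, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  stats::setNames(o$par, colnames(X))
}
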