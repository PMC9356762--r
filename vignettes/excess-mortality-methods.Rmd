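---
title: "Estimating excess and exiguous mortality from weekly death counts"
author: "exmort package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating excess and exiguous mortality from weekly death counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exmort)
```

## The problem

During a pandemic wave, deaths can rise (or fall) for reasons other than the
pathogen itself: strained hospitals, postponed care, changed end-of-life
arrangements. Quantifying these indirect effects requires a counterfactual —
how many deaths *would* have occurred in a given week absent the shock — and
a decision rule for when an observed count is genuinely aberrant. This
package implements that machinery for weekly death counts stratified by
underlying cause of death (ICD-10 groups), place of death (hospitals and
clinics, nursing homes and elderly care facilities, home, others), and
region, together with a synthetic-data generator so that the whole pipeline
can be exercised and validated without access to restricted vital-statistics
microdata.

## The baseline model

For a target week $t_0$, the expected count is estimated from historical
weeks with a quasi-Poisson regression

$$\log E(Y_t) = \alpha + \beta t + \gamma_{f(t)},
\qquad \mathrm{Var}(Y_t) = \phi\, E(Y_t),$$

where $t$ is the week index (units: weeks, on a continuous Monday-start
axis), $\beta$ a log-linear secular trend, and $f(t)$ a categorical seasonal
factor. Weeks whose circular offset from the target week's seasonal position
(offsets taken modulo 52; a 53rd week folds into offset 51's level) is
within $\pm w$ form the **reference window**, the factor's baseline level;
the remaining $52-(2w+1)$ offsets, traversed in increasing circular order
starting at $w+1$, are cut into `nSeason` consecutive blocks of equal length
(earlier blocks absorb any remainder). With the defaults $w=3$ and
`nSeason = 9` the off-season splits as $45 = 9 \times 5$, giving the
familiar 9+1-level seasonal factor.

Two baseline data modes exist. `FULL_HISTORY` (default) fits all
$52b$ weeks preceding the target; this is what the seasonal factor — dummies
for "time points outside the reference period" — presumes, and it is the
mode all calibration results below use. `WINDOW_ONLY` restricts the fit to
the reference-window weeks of the $b$ prior years (the original
window-restricted variant, no seasonal dummies); it is retained for
comparison because the algorithm family is often described that way.

### Fitting, dispersion, and downweighting

The model is fitted by IRLS (log link, relative tolerance $10^{-9}$, at most
100 iterations) with per-row prior weights. The dispersion is the weighted
Pearson $X^2/(n-p)$, **floored at 1**: allowing $\hat\phi < 1$ would shrink
prediction intervals below Poisson width and flag excess too eagerly. The
coefficient covariance is $\hat\phi\,(X^\top W X)^{-1}$.

Past aberrations (e.g. a previous year's heat wave) would inflate the
baseline, so rows whose Anscombe residual

$$r_i = \frac{3}{2}\,
\frac{y_i^{2/3} - \hat\mu_i^{2/3}}
     {\hat\phi^{1/2}\,\hat\mu_i^{1/6}\,(1-h_i)^{1/2}}$$

exceeds a threshold (default 2.58, the conventional choice in this
algorithm family) are downweighted to $w_i = k\,r_i^{-2}$ (others $w_i =
k$), with $k$ normalizing the weights to sum to $n$, and the model is refitted
once (`maxReweightIter` controls repeats). If nothing exceeds the threshold
the initial fit is returned unchanged.

### The trend rule

The original algorithm drops the linear trend when it is non-significant at
5%, when fewer than 3 years of history are available, or when the predicted
value exceeds every historical observation. National-scale mortality has a
slow, persistent demographic trend, and dropping it makes year-on-year
estimates jumpy; the default here is therefore `trendMode = "ALWAYS"` ($\beta t$
always retained). The conditional behaviour is implemented as
`"ORIGINAL_CONDITIONAL"` and switchable, since the choice is genuinely open.

### Prediction interval

The target week's expectation is $\hat\mu_0 = \exp(x_0'\hat\theta)$ with
variance $\widehat{\mathrm{Var}}(\hat\mu_0) = \hat\mu_0^2\,x_0'\hat\Sigma
x_0$; $x_0$ sits at the reference seasonal level. Bounds are computed on the
2/3-power scale, where Poisson-like counts are approximately symmetric:

$$U,\,L = \hat\mu_0\left(1 \pm z_{1-\alpha/2}\,\frac{2}{3}\,
\frac{\sqrt{\hat\phi\hat\mu_0 + \widehat{\mathrm{Var}}(\hat\mu_0)}}
     {\hat\mu_0}\right)^{3/2},$$

the inner factor floored at 0 before the 3/2 power, so $L \ge 0$ always. At
$\hat\phi = 1$ and negligible estimation variance, $U$ is within one count
of the exact Poisson 97.5% quantile at $\hat\mu_0 \in \{10, 100, 1000\}$
(the test suite checks this against pmf summation).

## Defining excess and exiguous deaths

A week is **excess** when the observed count strictly exceeds $U$, and
**exiguous** when it falls strictly below $L$ (equality is neither). Because
a point estimate of "how many extra deaths" is not meaningful when only a
threshold was crossed, excess deaths are reported as a **range**: from
$\max(0,\, y - U)$ up to $\max(0,\, y - \hat\mu_0)$, and symmetrically
$[\max(0, L - y),\ \max(0, \hat\mu_0 - y)]$ for exiguous deaths. The
excess/exiguous percentage divides each endpoint by $\hat\mu_0$.

Cumulative summaries sum the weekly ranges endpoint-wise. By default
**every** week contributes its $\max(0,\cdot)$ values, flagged or not: this
is the only rule that can produce nonzero cumulative high endpoints (ranges
like "0–X") over periods in which no single week was flagged, which is how
such summaries are conventionally presented. A `flagged_only` variant is
available for sensitivity analysis.

## Reporting-delay adjustment

Death registrations trail the event by days to weeks, so the most recent
~3 months of counts are provisional. The package uses a deliberately simple
multiplicative nowcast: from a reporting triangle (counts by event week and
delay $0..D$, default $D = 13$ weeks), the completeness
$\hat c_d = \sum_i C_{i,d} / \sum_i C_{i,D}$ is estimated over fully
observed event weeks, and a provisional week at delay $d$ is inflated to
$y/\hat c_d$ (rounded, never below the observed count). Fully reported weeks
are untouched. This is a documented stand-in for more elaborate nowcasting —
it propagates no uncertainty into the prediction intervals — and the
pipeline can bypass it entirely (`delayAdjust = FALSE`, or
`--no-delay-adjustment` in the CLI).

## The synthetic-data generator

`mortalityScenario()` / `simulateSeries()` generate weekly counts with the
statistical structure the estimator assumes to face: a log-linear trend plus
an annual sinusoid of period $365.25/7 = 52.1775$ weeks, negative-binomial
dispersion, multiplicative multi-week episodes, and binomial delay-thinning
of the trailing weeks. Defaults were chosen once to mirror a national
surveillance dataset at reduced scale: 492 Monday-start weeks beginning
2011-12-26 (so a weekly axis "starting in 2012" naturally includes the last
days of 2011), $\alpha = \log 1000$, $\beta = 5\times10^{-4}$/week (a
mortality level drifting upward a few percent per year, as in an ageing
population), amplitude 0.1 (winter/summer swing of roughly $\pm10\%$), and
size $k = 50$, i.e. local dispersion $\phi \approx 1 + \mu/k \approx 21$ at
$\mu = 1000$ — heavy but realistic for all-cause counts that mix
heterogeneous strata.

Two deliberate mismatches make the test-bed honest rather than circular:
the generator's seasonality is **sinusoidal** while the fit uses the
categorical 9+1-level factor, and its counts are **negative-binomial** while
the fit assumes quasi-Poisson (the two agree on the mean–variance relation
only locally, at $\phi = 1 + \mu/k$). Passing calibration therefore shows
robustness to moderate seasonal misspecification, not merely that a model
can recover itself. What the generator does *not* emulate: demographic
structure, population denominators, calendar effects (holidays), reporting
artefacts beyond stationary delay, and spatial correlation between regions —
so green tests here do not certify behaviour on real vital statistics with
those features.

`simulateRecords()` spreads each week's count uniformly over its seven days
and draws ICD-10 codes from per-category pools, so record-level
aggregation reproduces the weekly counts exactly (a conservation property
the tests assert), and `thinByDelay()` returns both the provisional view
and the true reporting triangle for round-trip checks.

## Calibration and power, at the scales the tests run

The package's headline check (also recomputed by `scripts/acceptance.R`)
simulates 500 null series — no episodes, 6 years of history plus 52
evaluation weeks, mean ~1000 deaths/week, $k = 50$ — and fits the default
model to each of the 26,000 evaluation weeks. The two-sided 95% interval
covers the observed count in about 93.5% of weeks. The shortfall from the
nominal 95% is expected and worth understanding: the bound is a normal
approximation on the power scale with a *plugged-in* dispersion, and at
$\phi \approx 21$ the neglected uncertainty in $\hat\phi$ plus the
approximation's tail behaviour cost roughly 1.5 points of coverage. The
power check injects a 4-week episode at multiplier 1.15 on a mean-5000
stratum with mild overdispersion ($k = 1000$, $\phi \approx 6$ — chosen as
typical of a large, more homogeneous stratum) and detects at least 3 of the
4 weeks in well over 90% of 200 replicates, with at most one false excess
flag in over 90% of matched null replicates.

Problem sizes used throughout the suite — 500 null series for calibration,
200 replicates per arm for power, 20 random fixtures for the
likelihood-oracle comparison, $10^5$-scale draws for delay-law recovery —
were picked as the smallest sizes at which the Monte Carlo error is clearly
inside the asserted bands.

## Numerical and degenerate-input choices

* IRLS tolerance $10^{-9}$ (relative deviance change), 100 iterations;
  non-convergence is flagged in the output, not fatal.
* Empty or aliased seasonal-level columns are dropped with a warning
  (common in sparse prefecture-level strata) rather than aborting the
  stratum; the run manifest records the warning.
* $\hat\phi$ floored at 1; leverages clipped just below 1 in the residual
  denominator.
* The interval's normal quantile at the default level is
  $z_{0.975} = 1.959964$.
* Insufficient history (series shorter than $52b$ weeks before the target)
  is a hard, named error — silently shortening the lookback would change
  the estimand.
* Recent pandemic-period history is *not* excised when estimating later
  targets: a baseline for a 2021 week legitimately uses 2020 data, because
  removing it would also remove the trend and seasonality information the
  model needs. Users wanting a stricter counterfactual can simply end the
  history earlier.

## ICD-10 grouping decisions

Codes are classified at 3-character block resolution, except that
4-character rules are checked first (R09.2 → respiratory; U07.1 →
COVID-19). The spelling "U7.1" is accepted and normalized to U07.1. U04
(SARS) is respiratory. U07.2 (clinically diagnosed COVID-19 without
laboratory confirmation) is **not** excluded from the non-COVID aggregate,
because only the confirmed code is named in the exclusion this grouping
follows; sites coding probable COVID-19 deaths to U07.2 can edit the
shipped plain-text mapping table (`inst/extdata/icd10_cause_map.tsv`) — the
mapping is data, not code. The respiratory category uses $b = 3$ by default
in the pipeline's per-cause overrides, the shorter history having been
found to fit that category better.

## Known limitations

* The flag is per-stratum at the 95% level with no multiplicity adjustment
  across the cause × place × region grid — intentional, matching
  surveillance practice, but users scanning many strata should expect ~2.5%
  false excess flags per week scanned.
* The interval is slightly anti-conservative at very high dispersion (see
  calibration above).
* The delay adjustment inflates point counts only; weeks adjusted upward
  carry no extra interval width.
* Excess/exiguous attribution is descriptive: crossing a prediction bound
  says nothing about *why* deaths rose or fell.
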