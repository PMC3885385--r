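---
title: "Measuring thermophilization of communities along elevational gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring thermophilization of communities along elevational gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Repeat presence/absence surveys of species communities along an elevational
gradient can reveal whether communities are reorganizing towards
warm-dwelling species ("thermophilization") and whether that reorganization
is uniform across altitudes. `thermocomm` implements the full chain of
analyses for such data: community-level thermal indices, their conversion to
a metres-denominated shift that is comparable across taxon groups, a
heteroscedastic regression of shifts on altitude with bootstrap inference,
and a mixed model testing whether air-temperature trends themselves depend
on altitude.

## Indices

Each species carries a species temperature index (STI): a scalar summary of
its temperature niche (an expert indicator value on a 1-5 scale for plants,
or the mean temperature across the species' larger range in degrees C for
mobile taxa). STIs are *inputs* here; the package does not derive them.

For a community (one sample square, one survey, one taxon group):

* CTI (community temperature index) = the unweighted arithmetic mean of the
  STIs of the species recorded. Occurrence-based by design: abundance
  weighting would let common species dominate, and the index is meant to be
  equally sensitive to rare and common species. `index_table()`
  deduplicates occurrences to presence/absence before averaging, so
  duplicated records cannot bias the index.
* CTV (community temperature variation) = the standard deviation of member
  STIs, measuring the thermal heterogeneity of the community. We use the
  sample SD (divisor n − 1), the unbiased-variance convention; the choice
  is inconsequential for any qualitative conclusion and is isolated in
  `compute_ctv()`.

A community with no species has no CTI (NA); CTV additionally needs at
least two species. Squares lacking an index in either survey are dropped
from the corresponding analysis only, which keeps the maximal data per
analysis. A species occurring without an STI entry is a hard error rather
than a silent drop, because silently dropping species biases the CTI.

## Standardization: from index units to metres

Raw CTI changes are not comparable across groups whose STIs live on
different scales. The standardization uses the group-specific slope *b* of
the first-survey index-altitude regression (fit by OLS in
`fit_altitude_slope()`). Dividing a temporal change by *b* expresses it as
the displacement along the gradient needed to find the same index value:

```{r}
library(thermocomm)
standardize_change(0.05, b = -0.001)
```

A temporal CTI gain of 0.05 in a group whose CTI falls by 0.001 per metre
of altitude corresponds to a quotient of −50 m — the same community
composition is found 50 m *downhill* — which we report with the
positive-uphill sign convention as an uphill community shift of +50 m. Both
numbers are returned; `shift_m = -raw_delta / b`. For CTV, positive
standardized values mean increasing thermal variability.

If a fitted *b* is zero or positive (possible on degenerate data), the
standardization aborts with a diagnostic instead of silently flipping the
interpretation.

## The shift-altitude model

Standardized shifts are modelled against polynomials of altitude centred at
500 m (so the intercept is the predicted shift for a lowland community at
500 m), optionally with the within-square altitudinal range as a raw-scale
covariate. Indices computed from richer communities are more precise, so
the residual SD is modelled as a function of species richness
(`fit_gls()`):

* fixed: constant residual SD (the ordinary linear model),
* power: SD proportional to richness^delta,
* constant plus power: SD proportional to c + richness^delta.

The variance covariate is the square's mean richness across the two
surveys, symmetric in the surveys whose difference is modelled (switchable
to survey-1 richness by passing that column instead).

`fit_gls()` maximizes the Gaussian likelihood directly, profiling the
coefficients (weighted least squares) and the scale; the REML criterion is
the exact likelihood of orthonormal error contrasts, so it matches a dense
multivariate-Gaussian evaluation to numerical precision (this identity is a
unit test). Model protocol, following the standard heteroscedastic-GLS
workflow:

1. variance structure chosen by REML AIC with the full fixed model held
   constant (`select_variance_structure()`),
2. fixed effects backward-selected by ML AIC, respecting the polynomial
   hierarchy — the cubic term is removable first, the linear term last, the
   intercept never (`backward_select()`),
3. final inference refit by REML, with REML likelihood-ratio tests for
   nested comparisons (`lrt_reml()`),
4. bootstrap confidence intervals and p-values for predictions at reference
   altitudes, by default 500 m and the 2350 m tree line
   (`bootstrap_predictions()`).

Numerical choices: variance parameters start at delta = 0 (and
log c = 0) with three jittered restarts, and are box-constrained to
delta in [−5, 5], log c in [−10, 10] — unconstrained search can drift to
degenerate corner solutions that assign essentially zero residual SD to
most observations; AIC differences below 1e−6 are ties, resolved towards
the simpler model; design columns are rescaled internally (the cubic
altitude column spans nine orders of magnitude), which leaves both
likelihood criteria unchanged.

## Bootstrap inference

The bootstrap is nonparametric case resampling: squares are drawn with
replacement, the already-selected model (fixed effects and variance
structure — no re-selection) is refit by REML, and predictions are made at
the target altitudes with the altitudinal-range covariate held at its
observed mean. Intervals are 95% percentile intervals; the two-sided
p-value is `2 min(#{pred <= 0} + 1, #{pred >= 0} + 1) / (B + 1)`, so an
interval excluding zero corresponds to p < 0.05. Case resampling was chosen
as the least model-dependent variant. Iterates that fail to converge are
redrawn (more than 10% failures is an error), and everything is
deterministic given a seed.

By default the standardization constant *b* is held fixed at its full-data,
first-survey estimate inside the bootstrap, matching the headline analysis.
`refit_b = TRUE` re-estimates *b* from each resample's first-survey values
and re-standardizes; this propagates the sampling error of *b* and is the
variant we use when checking interval *coverage*, since only then does the
interval account for both sampling layers.

Two caveats, both visible in our own simulations. First, intervals are
conditional on the selected fixed-effect specification: when backward
selection drops a genuinely present altitude term (low power), the 500 m
prediction collapses towards the gradient-average shift and no fixed-spec
interval can cover the truth — model-selection uncertainty is not
propagated. Second, with fixed `b` the intervals are mildly anticonservative
(a few percent) because `b`'s sampling error is ignored.

## The temperature-trend mixed model

Monthly station series are aggregated per station-year into the summer
(April-September) mean — requiring all six months — and the coldest-month
mean. `fit_temperature_lmm()` fits
`value ~ altitude + trend + altitude:trend` with crossed random intercepts
for station and year, by direct REML maximization over a dense marginal
covariance (at 14 stations x 16 years the covariance is only 224 x 224, so
no sparse machinery is needed). The trend is the year centred at the first
year of the window, so its coefficient is in degrees C per year, and the
interaction — the quantity of scientific interest, is the warming trend
altitude-dependent? — is in degrees C per year per metre, with altitude
left uncentred. Fixed-effect t statistics use a residual-df t reference
(n − p), which is approximate for mixed models; the simulation suite checks
that under a null trend the |t| > 2 rate stays modest. With a single year
of data the year variance is unidentifiable and is pinned to zero with a
warning.

## What the synthetic data emulate

`generate_species_pool()` + `generate_surveys()` emulate a national
biodiversity monitoring design: 214 1-km2 squares spanning roughly
263-2840 m, each surveyed twice five years apart. Species occupancy follows
a Gaussian response along altitude; STIs are strictly inversely ordered
against niche optima, so the expected CTI declines linearly with altitude
(slopes of the order −7e−4 to −1.5e−3 per metre, depending on the STI
scale). The imposed community change raises every species' effective
optimum in survey 2 by a shift that varies linearly with altitude — the
survey-2 community at altitude *a* is, in expectation, the survey-1
community from `shift(a)` metres downhill, which is exactly the
displacement the pipeline is supposed to recover.

Default study conditions, chosen once:

* butterfly-like group: 2000-species pool, STIs on 7-16 degrees C,
  maximal occupancy 0.10-0.20 — survey-1 richness about 27 per square,
  declining with altitude (`richness_decay = 2e-4` per m plus narrowing
  niches). The pool is deliberately denser than a real butterfly fauna,
  with occupancy scaled down to compensate: a sparse pool makes the
  *expected* CTI-altitude curve wiggle, so the estimand of the shift
  analysis would vary between pool draws instead of being the imposed
  shift. Density buys linearity; richness, which drives the statistical
  noise, stays at the monitoring scheme's level.
* plants-like group: 4000 species, Ellenberg-like STIs on 1-5, occupancy
  0.5-0.7 (richness ~215); birds-like: 2000 species, STIs 8-14 degrees C
  (richness ~30).
* niche widths 200-400 m (SD of the Gaussian response), narrowing with
  optimum altitude so that CTV declines with altitude, as observed
  gradients do; per-visit false-negative probability 0.1.

Presence is drawn independently per square and survey (no within-square
temporal persistence): the analysis models only the paired difference, and
independence makes null scenarios exact. The per-square noise of a
standardized shift is then roughly `sqrt(2) * width / sqrt(richness)` —
about 80 m for the butterfly-like conditions, matching the spread the
models estimate. Station series add a seasonal cosine, an altitudinal lapse
rate, station and year random intercepts, and measurement noise.

What the generator does *not* emulate: spatial autocorrelation between
squares, abundances, within-square persistence, land-use change, and any
pool-level turnover. Passing tests therefore show that the estimators
recover what this idealized process encodes — not that real communities
satisfy the model's assumptions. Cross-taxon survey-1 CTI correlations on
coupled synthetic communities are ~0.99, higher than real data, because all
groups respond to one shared altitude field with no additional ecological
structure.

## Problem sizes used in the test suite

The simulation tests run at the emulated design size (214 squares), with
100 replicates x B = 500 for the shift-recovery/coverage study and 200
replicates x B = 199 for the null calibration; likelihood oracles use small
instances (6 observations; 3 stations x 4 years) where dense brute-force
evaluation is exact. Selection-consistency and LRT-calibration simulations
use 30-500 replicates at n = 100-500. These sizes give binomial/Monte-Carlo
error small enough for the stated acceptance bands while keeping the suite
quick.

## Known limitations

* Percentile bootstrap intervals are first-order accurate; no BCa or
  studentized variant is provided.
* Model-selection uncertainty is not propagated into intervals (see above).
* The LMM's p-values use a residual-df t approximation; no Satterthwaite or
  Kenward-Roger correction.
* The GLS assumes independent residuals across squares; spatial correlation
  structures are out of scope.
* `standardize_change()` is a ratio estimator; with a noisy slope estimate
  it carries the usual mild ratio bias, which the `refit_b` bootstrap
  variant reflects but does not remove.
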