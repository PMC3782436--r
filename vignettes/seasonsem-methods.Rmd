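---
title: "Methods: CRA season descriptors and structural equation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRA season descriptors and structural equation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasonsem)
```

This vignette is the package's own account of its methods: the season
characterization, the SEM engine and specification search, the
synthetic-data generators, and the numerical and design choices behind
them.

## Season characterization from cumulative rainfall anomalies

The cumulative rainfall anomaly (CRA) on day $t$ is
$C_t = \sum_{s \le t} (r_s - \bar r)$, the running sum of daily rainfall
minus a constant reference rate.  By default the reference is the
long-term mean daily rainfall over the full record, so the CRA telescopes
to zero on the last day; any positive rate can be supplied instead.  The
CRA turns a spiky daily series into a waveform: it falls through the dry
season, bottoms out where the sustained rise begins, and peaks where the
rains end.

`detect_seasons()` places the wet-season **onset** on the day after the
CRA minimum within a per-year search window (default March 1 – July 31)
and the **cessation** on the day of the CRA maximum within a second
window (default August 1 – December 31).  The windows match a subtropical
climate whose wet season runs on average May 21 – October 1; both are
configurable.  A flat windowed segment (e.g. constant rainfall) yields a
per-year failure flag, never a crash, and flagged years are excluded from
the descriptor table with a logged count.  The exact turning-point rule
of the CRA literature admits variants (persistence criteria, smoothed
series); we implement the plain windowed extremum, and an optional
smoothing pass was deliberately left out because nothing downstream
requires it.

Durations count **both endpoints**: May 21 – October 1 is 134 days and
the complementary dry season October 2 – May 20 (crossing New Year) is
231 days, which pins the convention.  The dry season is labelled by the
calendar year of its onset.  February 29 stays in the daily grid; all
dates are computed on the real calendar.  Trend consistency is the $R^2$
of an ordinary least-squares line of the CRA against day index within the
season — near 1 when the drying or moistening trend ran uninterrupted,
lower when storms (dry season) or droughts (wet season) punctuated it.

Season-mean Niño 3.4 values are day-weighted: each month intersecting the
onset–cessation span contributes its monthly value weighted by the number
of season days inside that month, so the weights sum to the season
duration and incomplete months are proportionately represented.

## Normality transforms

The descriptor variables are skewed, and each enters the SEMs through a
fixed transform: square root for fire counts and area burned, natural log
for wet-season duration and rainfall, $\log_{10}$ for dry-season onset
date, squaring for wet-season onset and dry-season duration, and for
trend consistency the reflected log $y = |\ln(1 - x)|$ — the
reflect/log/re-reflect recipe for scores bounded just below 1, collapsed
into a single strictly increasing formula.  No offset constants are
introduced: the logged variables are strictly positive by construction,
and $\sqrt{0} = 0$ is legitimate for counts.  Transforms are screened
with Shapiro–Wilk tests (delegated to `stats::shapiro.test`).

## The SEM engine

Models are recursive (acyclic) linear-Gaussian systems over observed
variables, covariance structure only — no mean structure, latent
variables, or multi-group features.  With coefficient matrix $A$ and
exogenous/error (co)variance matrix $\Omega$, the implied covariance is
$\Sigma(\theta) = (I-A)^{-1}\,\Omega\,(I-A)^{-\top}$.  Estimation
minimizes the ML discrepancy
$F(\theta) = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p$
against the sample covariance $S$ (computed with the $n-1$ denominator),
giving the classical $\chi^2 = (n-1)F$ on $p(p+1)/2 - q$ degrees of
freedom for $q$ free parameters.

Numerical choices, in order of consequence:

* **Internal standardization.**  $F$ is invariant under separate
  rescaling of the variables, so the optimizer always works on the
  correlation-metric problem and maps estimates (and standard errors)
  back afterwards.  Raw descriptor scales differ by nine orders of
  magnitude (squared durations vs. reflected-log scores); without this
  the quasi-Newton steps are badly conditioned.
* **Positivity by parameterization.**  Variances are optimized on the
  log scale; a Heywood case therefore appears as an error variance
  collapsing toward zero (flagged when it falls below $10^{-7}$ of the
  variable's own variance) rather than as a negative estimate.
* **Warm starts.**  The first start is the per-equation least-squares
  solution — for recursive models with uncorrelated errors this is
  already the global ML optimum, so BFGS converges in a few iterations —
  and the remaining deterministic starts rescale its coefficients
  (factors 0, 0.5, 1.5, −0.5) to guard against local minima when
  coefficients are fixed.  Convergence requires a gradient max-norm of
  $10^{-8}$ (analytic gradients via
  $dF = \mathrm{tr}[\Sigma^{-1}(\Sigma - S)\Sigma^{-1}\,d\Sigma]$).
* **Standard errors** come from the inverse observed information
  (numerical Hessian of $F$, scaled by $2/(n-1)$), computed in the
  standardized space and rescaled.
* **Saturated models** report $\chi^2 \approx 0$ with $df = 0$ and an
  undefined p-value (`NA`).

Standardized coefficients multiply each raw coefficient by the implied
SD of its source over the implied SD of its target; $R^2$ of an
endogenous variable is one minus its error variance over its implied
variance.  Significance tiers for diagram export follow the usual
line-weight coding (dashed non-significant; increasing weights at
$p \le 0.10$, $0.05$, $0.01$, $0.001$).

**Exogenous covariances default to zero** unless declared.  This
convention reproduces the degrees of freedom of all the catalog's
starting models (e.g. five variables, four arrows, $q = 9$, $df = 6$ for
the dry-season starting model); the saturated wildfire framework instead
declares the covariance between its two exogenous drivers so that the
full model reaches $df = 0$.

Effects decompose as direct (the edge coefficient), indirect (the sum
over all directed paths of length $\ge 2$ of the products of standardized
coefficients, computed as $(I-A)^{-1} - I - A$), and total (their sum).
`path_products()` enumerates the individual routes, which is how printed
mediation arithmetic such as $-0.69 \times 0.46 = -0.32$ is checked.

## Model selection

The specification search enumerates every subset of a framework's
optional arrows — exactly $2^k$ candidates, in lexicographic mask order —
fits each by ML, and ranks admissible fits by the Browne–Cudeck
criterion, $\mathrm{BCC} = \chi^2 + 2q(n-1)/(n-p-2)$ (single-group
covariance form; the per-parameter penalty exceeds the AIC's 2 for every
admissible $n$).  Ties break toward fewer free parameters, then the
candidate mask, making the ranking a documented total order.
Non-identified candidates are skipped; non-converged and Heywood fits are
listed separately rather than ranked.  During the sweep candidates are
fitted warm-started without standard errors; the reported top models are
refitted with the full start set and SEs.

Two caveats about published criterion values.  First, the BCC constant
used by commercial SEM software cannot be reverse-engineered from the
values printed for this system (models with equal df show unequal
BCC − χ² gaps, which no single-group covariance-only formula produces),
so catalog BCCs are not comparison targets; χ², df and p are.  Second,
the wildfire starting model is printed once with df = 3 and once with
df = 4; the six-arrow structure with independent exogenous drivers gives
df = 4, and the analytic p-value (0.054) matches the printed 0.05, so the
catalog uses df = 4.

The saturated seasonal framework orders the variables
Niño 3.4 → onset → duration → rainfall → trend consistency and includes
every forward arrow (ten optional edges, $df = 0$ when all are present).
The original figure does not spell out whether reversed arrows were ever
candidates; the forward ordering follows the causal logic of the
starting models and is recorded here as an assumption.  By default *all*
framework arrows are optional (the search may drop theory arrows);
`mandatory = "starting"` pins them instead.

## Synthetic data

Two generation levels serve different tests.  The **descriptor-level**
sampler draws exact multivariate-normal tables from any fully specified
catalog model (population covariance = implied covariance), so the SEM
engine is tested without CRA noise.  The **daily-level** generator builds
a mechanistic climate: per-year wet-season boundaries jittered around
May 21 / October 1 with SD 30 days (about a month, matching the site's
interannual spread), daily rainfall as a Bernoulli–gamma storm process
whose event probability and mean depth switch between regimes, a monthly
AR(1) ENSO index (coefficient 0.92, marginal SD 0.85 °C), and a
log-linear, mean-preserving modulation of dry-season event depth by the
concurrent monthly index (coefficient 0.15).  Rates are calibrated so the
long-term seasonal totals match the site's 89 cm (wet) and 42 cm (dry)
means; with the boundary jitter they also reproduce seasonal-total SDs of
roughly the observed order (≈ 27 and ≈ 15 cm).

The storm process is deliberately milder in day-to-day variance (event
probability 0.85 wet / 0.35 dry, gamma shape 3) than real convective
rainfall, where single days can dominate a month.  Real records will
therefore localize CRA turning points somewhat less precisely than the
synthetic benchmark; passing the recovery tests shows the detector is
correct and well-behaved, not that ±7-day accuracy is guaranteed for any
station record.  Trend consistency is not given a distributional form of
its own: at the daily level it emerges from the CRA, and at the
descriptor level it is sampled on its reflected-log scale.

Annual fire records are generated on the standardized square-root scale
from the configured path coefficients (defaults: the second-best
wildfire model) plus Gaussian noise, back-transformed, with counts
rounded and negatives truncated at zero; truncations are counted and
reported because they perturb the Gaussian assumption the refitting
tests rely on.

The fire table aligns fire year $t$ with the dry season labelled $t-1$
(which spans the fire season) and with the trend consistency of wet
season $t-1$; the one-year shift drops the first year and is logged.

## Test problem sizes

The suite exercises the engine at the sizes the analysis itself uses:
58 season-years and 30 fire-years for sign-recovery (100 replicates
each), n = 5000 for coefficient recovery (within ±0.05), 500 replicates
for χ² calibration at n = 58 (rejection rate at α = 0.05 within
[0.02, 0.10]), 50 large-n replicates for the 32-candidate search
benchmark, and three 58-year synthetic climates for boundary recovery
(within ±7 days for ≥ 90 % of years).  The ML engine is cross-checked
against an independent closed-form route — for recursive models the
likelihood factorizes into per-equation least squares — on twenty random
3–5-variable models to within $10^{-3}$.

## Known limitations

* Covariance structure only: no means, intercepts, latent variables,
  missing-data FIML, or non-ML estimators.
* The season detector assumes one wet season per calendar year inside
  fixed search windows; bimodal rainfall regimes need different windows
  and were not a design target.
* The weather generator has no spatial structure, temperature, or
  tropical-cyclone extremes; its role is ground-truth recovery testing,
  not climate realism.
* Standardized coefficients can exceed 1 in magnitude when predictors
  are strongly collinear (duration and rainfall); this is a property of
  partial coefficients, not an error, but it complicates effect-size
  comparison.
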