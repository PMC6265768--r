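---
title: "Methods: threshold distributed-lag modelling of cold-related mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold distributed-lag modelling of cold-related mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldsnap)
```

## The problem

Cold outdoor temperature raises mortality with a delay: deaths accumulate
for up to about four weeks after a cold spell, through cardiovascular,
respiratory and other pathways. Quantifying this at small-area level
requires (i) a single daily temperature series per area built from several
imperfect weather stations, (ii) a count regression that separates the
lagged cold effect from seasonality, secular trend and weekday patterns,
and (iii) summaries a public-health planner can act on: a cumulative
relative risk, an attributable share of winter deaths, the change since an
intervention, and a rule for flagging areas whose need appears unmet.
`coldsnap` implements that chain, plus a generator of synthetic studies
with known truth so every stage can be validated.

## Composite temperature

Stations reporting on fewer than 75% of study days are dropped
(`coverage_filter()`; the fraction is configurable, and an area with no
surviving station is an error rather than a silently absent result).
Remaining stations are combined by **anomaly averaging**
(`composite_mean()`): each station's mean — computed over the days it
shares with at least one other station — is subtracted, the anomalies are
averaged across the stations reporting each day, and the result is
re-centred to the pooled mean of all observations. Averaging raw values
instead would let a systematically cold station's missing days push the
composite warm on exactly the days it is absent; anomaly averaging removes
that bias while preserving day-to-day variation. With a single station the
composite equals that station's series.

Remaining gaps are filled by `impute_missing()`: a natural cubic spline on
day of year (default 6 df) is fit to the observed days, and observed
residuals are linearly interpolated across interior gaps (edge gaps take
the seasonal prediction alone). Observed days are never altered. Guards:
at least 90% of days must be observed and no gap may exceed 30 days
(both configurable) — beyond that a seasonal model would be fabricating
weather, so the function fails instead. The imputation sits behind a
single function so an alternative scheme can be swapped in.

Temperature summaries (`summarize_temperature()`) use type-7 quantiles
(linear interpolation between order statistics); the 1st-percentile values
that anchor the risk contrasts depend on this convention, so it is fixed
and stated. Summaries are winter-only by default (November–March), with a
flag for all-year summaries.

## The threshold distributed-lag model

For winter day $t$ in area $a$ (winters are independent series; each
winter is labelled by the year of its January):

$$\log \mu_t \;=\; \alpha + \sum_{l=0}^{L} \eta_l\, z_{t-l}
 \;+\; f_{\text{season}}(\text{winter day}_t) + f_{\text{trend}}(t)
 \;+\; \gamma_{\text{dow}(t)},
 \qquad z_t = \max(0,\, h - T_t),$$

with $Y_t$ quasi-Poisson around $\mu_t$. Assumptions worth stating
explicitly:

* **Threshold-linearity.** Risk is null at and above $h$ and log-linear in
  degrees of cold below it. The default $h$ is the area's maximum winter
  temperature, so "cold" is defined relative to the area's own climate;
  a fixed common threshold (e.g. 13 °C, or 0 °C contrasts) is available
  for sensitivity analyses via the `threshold` argument.
* **Lag structure.** $L = 28$ days. The lag curve $\eta_l$ is a natural
  cubic spline over lag with 4 df, intercept included (so a flat profile
  is representable), interior knots equally spaced on the log-lag scale —
  lag effects change fastest at short lags. An identity (29-column) basis
  is available and is used by the exact oracles in the tests. The true
  lag profile is not identifiable from cumulative summaries, which is why
  the generator offers several shapes (below).
* **Group boundaries.** A day's lag window must lie entirely inside its
  own winter: the first 28 days of each winter are excluded from the
  outcome rows. This mirrors treating winters as multiple independent
  series and avoids borrowing exposure across summers.
* **Controls.** Seasonal variation: natural cubic spline on day-within-
  winter (days since 1 November), default 4 df. Trend: natural cubic
  spline on calendar time, default one df per winter of data (dropped
  when only a single winter is present, where it would be collinear with
  the seasonal spline). Day-of-week: six indicators, Sunday absorbed in
  the intercept. The defaults are deliberately modest: winter series are
  short, and the recovery study below is the evidence that they suffice
  under the generator's conditions.

Rank deficiency of the assembled design is detected block by block and
reported with the offending block's name (a constant cold-excess series,
for example, makes the cold block collinear with the intercept).

## Fitting

`fit_quasipoisson()` is iteratively reweighted least squares with log
link: point estimates coincide with the Poisson MLE; the covariance is
$\hat\phi\,(X^\top W X)^{-1}$ with $\hat\phi$ the Pearson statistic over
residual degrees of freedom. Starting values are zero except the intercept
at $\log(\bar y + 0.5)$; convergence is a relative deviance change below
$10^{-9}$ (at most 100 iterations; non-convergence is flagged and
warned, not hidden). The linear predictor is capped at 30 during
iteration to avoid overflow in early steps. Zero-death days are ordinary
observations. The tests pin this fitter against both
`stats::glm(family = quasipoisson)` and direct numerical maximization of
the Poisson likelihood.

## Risk summaries

* `rr_between(fit, t_from, t_ref)`: the cumulative contrast multiplies
  the change in cold excess by the column sums of the lag basis;
  $\mathrm{RR} = \exp(c^\top \beta)$ with Wald 95% intervals, symmetric on
  the log scale (published intervals of this kind are asymmetric on the
  RR scale in exactly this way). Below the threshold, risks compose
  multiplicatively over sub-intervals — a tested identity.
* `attributable_burden()`: backward perspective — each day's deaths are
  attributed to the cold excess of its own past 28 days,
  $AF_t = 1-\exp(-\sum_l \eta_l z_{t-l})$, summed with weights $Y_t$.
  The counterfactual is the threshold temperature, where the effect is
  null by construction.
* `split_periods()`: a winter belongs whole to a period. Defaults: pre =
  Januaries 2007–2010, post = Januaries 2013–2015. The winters spanning
  2010/11 and 2011/12 fall in neither: the intervention was introduced
  during autumn 2011, so its first winter is transitional, and assigning
  it to the post period would dilute any contrast. Both windows are
  arguments, so other conventions are one call away. Period refits in
  `run_pipeline()` reuse the full-period threshold and contrast
  temperatures, so a pre/post change reflects the association, not a
  shift in the temperature distribution between periods.
* `compare_rr()`: two-sample z-test on log RR with standard errors
  recovered from the intervals, $se = (\log hi - \log lo)/(2 \cdot 1.96)$;
  two-sided $\alpha = 0.05$ throughout.

## Heterogeneity and the needs rule

`i_squared()` is the fixed-effect Cochran's Q with
$I^2 = \max(0, 100\,(Q - df)/Q)$, clamped at zero. The national row is
data, not a pooled estimate, and is excluded from between-area statistics.

`classify_need()` flags an area when its pre-to-post change in **log** RR
strictly exceeds the median area's change and its fuel poverty strictly
exceeds the national percentage. Choices made where the rule was
genuinely open: the change metric is the log-RR difference (symmetric;
a ratio-of-RRs variant is the same rule on the same scale), the median is
over all areas, ties at the median or at the national fuel-poverty value
are *not* flagged, and the national comparator is supplied as data rather
than recomputed as an unweighted mean of areas. For "significantly above
the national estimate", CI non-overlap (`count_exceeding_national()`,
default) is used rather than a z-test: on the packaged 45-row estimate
table the non-overlap criterion yields exactly the two published areas,
while the z-test flags a third — both are implemented, and the tests pin
both behaviours.

## The synthetic-data generator

`simulate_study()` emulates the structure of the real inputs: a latent
area temperature (annual cosine cycle, coldest mid-January, plus AR(1)
anomalies, default coefficient 0.7 and innovation SD 1.8 °C — values in
the range of English daily series); stations observing that latent series
with systematic offsets (SD 0.8 °C), measurement noise (SD 0.6 °C) and
days deleted independently (default 10%, with at least one station
guaranteed to pass the 75% filter); and death counts whose log mean adds a
winter-peaking seasonal cycle (amplitude 0.15 on the log scale),
day-of-week offsets summing to zero, and the distributed-lag cold term.
Counts are negative binomial parameterised to variance $\phi\mu$
(quasi-Poisson has no generative form; this matches the fitted model's
first two moments and reduces to Poisson at $\phi = 1$). Defaults mirror
an England-like study: 44 areas, nine years from 2007, ~20 stations per
area, baseline 30 deaths/day per area, cumulative log RR
$\log(1.35)/17.27$ per °C of cold excess (the national-scale effect
spread over a typical P1-to-maximum span), threshold 13 °C,
overdispersion 1.5, fuel poverty uniform on 7–15%.

Lag weights come in three shapes (`constant`, `linear-decay`,
`spline-bump`, the last a smooth bump peaking near lag 6 — the classic
delayed cold-mortality profile); the cumulative effect, not the shape, is
what the estimators target. Twenty-eight pre-period days are generated
before 1 January so the first study day has a full exposure history —
generator edge effects are never confounded with the fitter's
group-boundary policy. Everything is deterministic given the
configuration seed, with independent streams per area and purpose.

What the generator does **not** emulate: influenza epidemics, air
pollution, age structure, spatially correlated station networks, or
measurement artefacts like sensor drift. Passing recovery tests therefore
demonstrates internal consistency of the estimation chain under
realistic-looking noise — not robustness to the confounders a real
analysis must argue about separately.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` run, at sizes chosen to make
Monte-Carlo error small while keeping a laptop-scale runtime:

* **Recovery** (`recovery_study()`): 200 single-area replicates of nine
  winters, baseline 30 deaths/day, overdispersion 1.5, spline-bump lag
  weights, true cumulative RR 1.4 between each replicate's realised
  winter P1 and maximum; checked for mean log-RR bias below 0.02 and 95%
  CI coverage between 90% and 98%.
* **Oracles**: IRLS vs brute-force likelihood maximization on twenty
  $n = 50$ instances (agreement to $10^{-6}$); the lag block vs an
  $O(nL)$ double loop (machine precision); the attributable number vs an
  independent per-day recomputation.
* **Null safety** (`null_coverage_study()`): 100 replicates with the cold
  effect off; the 95% interval should contain 1 in at least 90% of them,
  and a zero lag-coefficient vector attributes exactly zero deaths.
* **Needs** (`planted_needs_study()`): nine areas, four with the cold
  effect tripled after the transition, fuel poverty planted so exactly
  two worsened areas sit above the national value; the estimated flags
  must equal the planted truth.

## Known limitations

* The imputation scheme is a pragmatic seasonal-spline-plus-residual
  interpolation, not a reimplementation of any specific published method;
  it is deliberately replaceable.
* The headline model is threshold-linear; a smooth non-linear exposure
  curve is available only descriptively (`plot_exposure_response()` shows
  the cumulative curve implied by the threshold model, not a free-form
  fit).
* Attributable-number intervals (empirical CIs) are not computed; no
  multiplicity adjustment is applied across areas.
* Strata (age bands, causes) are opaque labels: the package will fit
  whatever series it is given and leaves small-count judgement to the
  analyst.
* With fewer than two areas heterogeneity is undefined and skipped; with
  few areas the median in the needs rule is fragile, and flags should be
  read descriptively.
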