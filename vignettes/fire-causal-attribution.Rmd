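---
title: "Causal attribution of wildfire burned area: model, assumptions, and design choices"
author: "fireCausal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal attribution of wildfire burned area}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireCausal)
```

## The scientific question

Weekly burned area (BA) in a region co-varies with two families of
precursors: top-down weather variables (Tmax, VPD, ET0, wind, aridity
anomaly) that set flammability, and bottom-up fuel variables (FPAR, GPP,
NDVI, EVI, soil water deficit) that set fuel amount and condition. The
package estimates, per ecoregion (climate zone × vegetation type), which
precursors are *causal parents* of BA, at which time lags, and which
family dominates. Dominance separates flammability-limited regimes (fires
whenever the weather allows; short lead times) from fuel-limited regimes
(fires when fuel has accumulated; seasonal-to-interannual lead times where
fuel management can act).

## The statistical model

The unit of analysis is a `FirePanel`: a T × N matrix of weekly anomalies,
one column tagged `target` (BA) and ten tagged with their precursor group.
Causal discovery assumes (a) *causal sufficiency* — the relevant drivers
are among the panel variables — and (b) *stationarity* — achieved
approximately by removing the linear trend and the mean seasonal cycle.
Both assumptions are approximations for real data; the preprocessing
module exists to make (b) defensible, and (a) motivates including all ten
precursors rather than a chosen few.

### Stage 1: condition selection

For each variable Y, candidates are all lagged pairs (X, τ) with
τ ∈ [max(τ_min, 1), τ_max]. At conditioning dimension q = 0 each candidate
is tested unconditionally against Y_t; for q = 1…q_max each survivor is
tested conditional on the q currently strongest *other* survivors (ranked
by the minimum |ρ| seen so far), with removal applied after each full pass
so the result does not depend on within-pass ordering. Survivors form the
parent set 𝒫(Y). All selection tests share the sample t = τ_max+1…T so
strengths are comparable across lags.

### Stage 2: momentary conditional independence

Every ordered pair (X, Y) and lag τ (τ ≥ 1 when X = Y) is tested:
X_{t−τ} ⟂ Y_t given 𝒫(Y) \ {(X, τ)} together with 𝒫(X) shifted by τ, each
side truncated to its `maxConds` strongest members. The statistic is the
linear partial correlation — Pearson correlation of the OLS residuals of
each endpoint on the conditioning block — with a two-sided t test on
n − |Z| − 2 degrees of freedom. Conditioning on *both* parent sets is the
step that keeps false positives at the nominal level even under strong
autocorrelation. Links with p ≤ α are retained; the full ρ/p/sample-size
arrays are kept for audit.

### Attribution

Per ecoregion, each precursor is represented by its strongest retained
link into BA (max |ρ|; ties resolve to the smaller lag, then the
lexicographically smaller identifier — a fully deterministic rule). The
first-ranked precursor is the dominant precursor, its lag the dominant
lag, and its group the dominant group. The predictability score is Σρ²
over the precursors' strongest links (0 when nothing is retained — the
"no causal relationship detected" state). Group-level lags are |ρ|-weighted
means; cross-ecoregion group lags are additionally area-weighted over the
ecoregions the group dominates. Covariate profiles bin pixels into 200
equal-width bins over the observed covariate range and report, per bin,
each group's share of the *dominated* pixels (undetected pixels are
excluded from the denominator, so defined fractions sum to 1).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | significance level for link retention (MCI stage) |
| `tauMax` | 156 wk | maximum lag searched (3 years of weekly lags) |
| `tauMin` | 0 | contemporaneous links admitted (see below) |
| `pcAlpha` | = `alpha` | selection-stage level; one level for both stages |
| `qMax` | 3 | conditioning-dimension cap of the selection stage |
| `maxConds` | 5 | per-side conditioner cap of an MCI test |
| mask threshold | 70% | BA pixel-weeks with confidence strictly below are dropped |
| weighting | cosine | precursor pixel weights in the ecoregion mean |

`qMax` and `maxConds` bound compute (at τ_max = 156 there are ~1,700
candidates per target) while preserving the algorithm's character; both
are exposed on `pcmciConfig()`. No multiple-testing correction is applied
beyond the two-stage design itself; an optional Benjamini–Hochberg
post-filter over the MCI p-matrix exists but is off by default.

## Design choices where the design was open

* **Contemporaneous links.** τ_min = 0 is admitted because realistic
  precursor–fire lags include "same week". A significant lag-0 association
  between a precursor and BA is oriented precursor → BA a priori (same-week
  weather/fuel state can affect burning; same-week reverse causation is
  excluded by construction), and lag-0 links between two precursors are
  discarded. This orientation is an assumption, not an inference.
* **Anomaly definition.** Anomalies subtract a linear trend over the whole
  record and the multi-year mean at each week of year, with no smoothing
  window and no standardization. The panel pipeline fits both components
  as one joint OLS projection (trend term + week-of-year indicators):
  residuals are then exactly orthogonal to the trend *and* have exactly
  zero mean at every week of year, whereas applying the two steps
  sequentially leaves a small leakage term because a sampled seasonal
  cycle is not exactly orthogonal to a linear trend. The standalone
  operations `detrendLinear()` and `removeSeasonalCycle()` remain
  available as primitives. The week convention is fixed 52-week years
  (week w = days 7(w−1)+1…7w; week 52 absorbs days 365/366).
* **log1p for BA.** Weekly BA has exact zero weeks, so the
  variance-stabilizing transform is log(1 + x) (configurable offset),
  zero-preserving and defined everywhere. It is applied to the
  *ecoregional* BA sum, i.e. to the series the causal test consumes.
* **Ecoregion aggregation.** BA is the plain sum of member-pixel BA
  (masked pixel-weeks contribute nothing); precursors are
  cosine-of-latitude area-weighted means (uniform weighting available).
* **Tie-breaking and zero signs.** Everywhere: larger |ρ| → smaller lag →
  lexicographic identifier; ρ = 0 counts as positive in sign fractions.
  These are measure-zero events whose handling must still be
  deterministic and platform-independent.
* **Lag weights.** Group mean lags weight by |ρ|, not signed ρ: a signed
  weighting can produce a zero denominator and a negative "importance"
  has no interpretation.
* **Predictability score over retained links only.** Non-significant
  precursors contribute 0; the audited ρ matrix is available if a user
  wants the all-links variant.

## The synthetic generator

`scenarioSpec()` declares a panel's data-generating process exactly: a
lagged linear system over the declared variables (planted links plus
optional AR(1) memory), Gaussian innovations, a sinusoidal seasonal cycle,
and a linear trend. Validity checks reject unstable systems (companion
matrix spectral radius ≥ 1) and records shorter than twice the longest lag
plus 100 weeks. The target can be rendered through a zero-inflated expm1
marginal: the latent series is thresholded at its zero-inflation quantile
(exact zeros below) and exponentiated above, so the observed BA is
non-negative, right-skewed, zero-inflated — and the preprocessing log1p
approximately recovers the latent Gaussian series, making the transform
testable round-trip. This zero-inflation mechanism is a modeling choice of
the package (the marginal of real weekly ecoregional BA is known only to
be skewed).

`simulateScene()` lays panels onto a classified grid: each ecoregion's
signal is observed by its member pixels plus independent pixel noise, and
a percent-confidence layer is drawn per pixel-week from a declared
discrete distribution so the quality-masking rule is exercised. Ground
truth per ecoregion is the group owning the planted link of largest
absolute standardized effect into BA.

What the generator does *not* emulate: the spatial patterns, units, and
ranges of real satellite products; spatially correlated pixel noise;
regime shifts or non-constant causal structure; climate-mode
teleconnections. Passing tests therefore demonstrate that the *machinery*
recovers planted structure under realistic statistical nuisances — not
that any particular real-world attribution is correct.

## Study conditions used by the tests

The package's reference experiment (`syntheticStudy()`) fixes: 50
ecoregions × 4 pixels, 936 weeks (18 years), dominant planted coefficient
0.65, a 0.25-coefficient secondary link from the opposite group, AR(1)
0.5 precursor memory, seasonal amplitude 2 (precursors) / 1 (BA), trend
0.001/wk, BA zero inflation 0.35, pixel noise sd 0.2, and a confidence
distribution with 10% of mass below the 70% threshold. Top-down links are
positive at lags 0–4 weeks; bottom-up links negative at lags 20–70 weeks,
mirroring the short-lag/flammability vs long-lag/fuel structure of the two
groups. Discovery on this scene uses τ_max = 80 weeks, which spans every
planted lag with margin while keeping the full suite's runtime moderate;
the null-calibration benchmark uses 500 panels of 5 white-noise series
(T = 500, τ_max = 5).

## Numerical policy and degenerate inputs

OLS inside the CI test uses a QR factorization with a rank check; a
rank-deficient conditioning block falls back to a pseudoinverse solve
internally, while the user-facing `partialCorrelation()` drops redundant
conditioners with a warning. ρ is clipped to [−1, 1]; residuals with
numerically zero variance yield a degenerate result with p = 1 rather
than an exception mid-scan; tests with effective sample n − |Z| − 2 < 10
are flagged missing. Missing data are handled by listwise deletion over
the union of lagged index sets of each individual test, and anomalies at
missing entries remain missing — there is no gap-filling.

## Known limitations

* Linear partial correlation only: nonlinear or threshold dependencies
  are represented only through their linear component.
* The lag-0 orientation rule is an assumption; the method cannot orient
  contemporaneous links from data.
* At α = 0.05 over ~10 × τ_max tests into BA per ecoregion, a handful of
  near-threshold false links per ecoregion is *expected*; group mean lags
  pooled over all links are therefore noisier than the dominant lag, and
  downstream users should prefer the dominant link's lag when a single
  number is needed.
* Real-data mode expects gridded inputs already ingested into the scene
  container; the package ships no NetCDF/GeoTIFF reader and writes plain
  CSV/JSON.
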