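---
title: "Counterfactual potential biomass: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual potential biomass: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(potbiomass)
```

## The problem

Deforested landscapes carry less above-ground biomass (AGB) than the
climate could support. The gap between the two — the *biomass deficit*
— is the net, cumulative imprint of human disturbance: clearing pushes
it up, regrowth pulls it down, and a changing climate moves the ceiling
itself. `potbiomass` estimates that ceiling, the *potential* AGB
(AGB~pot~), for every pixel of a gridded domain and every year of an
observation record, and derives the deficit
AGB~def~ = AGB~pot~ − AGB~obs~ with an observation-uncertainty
envelope.

The estimation idea is a space-for-time substitution. Intact-forest
pixels are, by assumption, at their climatic potential. A regression
model trained on those pixels — observed AGB as a function of the local
monthly climatology and latitude (a photoperiod proxy) — captures the
climate envelope of undisturbed biomass. Applying it to the disturbed
part of the basin yields the biomass those pixels would hold under the
same climate had they never been cleared. Because the model is refit to
each year's intact-forest AGB against a *static* climatology, all
interannual variation in the reconstruction reflects how that year's
conditions moved stocks inside the intact zone; potential maps inherit
the climate signal without ever seeing a disturbed pixel's history.

## The regression engine

The core model is a bagged ensemble of *model trees*: binary decision
trees whose terminal nodes hold multiple linear regressions rather than
constants. Each of `n_trees` trees (1,000 at full scale; 100 is the
package's reduced default for routine runs) is grown on a bootstrap
resample of the training pixels. Prediction is the arithmetic mean over
trees, floored at zero.

Several details are deliberate choices the method statement leaves
open, fixed here once:

* **Split criterion.** Reduction in the target sum of squares, the
  standard regression-tree criterion. At each node `mtry` candidate
  features are drawn (default ⌈√(p+1)⌉ of the p continuous features
  plus the open-water flag); thresholds sit at midpoints of adjacent
  sorted values; criterion ties break toward the lowest feature index,
  then the lowest threshold, which makes fits reproducible to the bit.
* **Leaf regressions.** Ordinary least squares on *all* continuous
  features. A leaf with fewer than p + 2 rows, or a rank-deficient
  design, falls back to the leaf mean and is flagged. The default
  minimum leaf size, 2·(p + 1), keeps leaf regressions at worst barely
  determined.
* **Leaf extrapolation bounds.** Monthly climatology layers are heavily
  collinear (one seasonal cycle spans most of the variance), so
  unguarded leaf OLS can acquire enormous coefficients along
  near-null-space directions and explode when applied slightly outside
  the leaf's support. Following the long-standing practice of
  model-tree systems, each leaf's prediction is clamped to the range of
  its training targets stretched by a fixed margin. The margin trades
  protection against collinear blow-ups (which are orders of magnitude)
  against the genuine linear extrapolation the leaves exist to provide
  near the envelope edge; the default (see `fit_forest()`) was chosen
  on synthetic worlds before the acceptance thresholds were evaluated,
  and `bound_extrapolation = FALSE` restores pure OLS leaves (used in
  the oracle-equivalence tests, which demand an exact OLS identity).
  Classic model-tree path smoothing (blending each prediction with
  ancestor-node regressions) is available via the `smoothing` constant;
  it is off by default, so the default prediction is the plain mean of
  leaf regressions.
* **Categorical open-water flag.** Large open-water pixels carry a
  time-constant observation, so they are separated by a binary split
  feature rather than by their (distorted) climatology. The flag only
  routes rows; it never enters a leaf design matrix.
* **Determinism.** One master seed; per-tree seeds are drawn once up
  front, and rows are canonicalised by pixel index before fitting, so
  the fit is invariant to input row order and to the order trees are
  evaluated in.

The ensemble is serialised to a versioned JSON document in which reals
are written as 17-significant-digit decimal strings; restored forests
predict bit-identically.

## The pipeline

For each year and each observation quantile level (5th percentile,
mean, 95th percentile) an independent forest is trained on the intact
pixels and applied to the disturbed zone; running the full pipeline per
level propagates the observation-map uncertainty into confidence ranges
on every downstream quantity. Intact pixels are at potential by
definition, so their AGB~pot~ is their observed value and their deficit
is identically zero; all basin totals are restricted to the disturbed
(basin-minus-intact) zone. Totals weight each pixel by its geodesic
cell area (mean Earth radius 6,371,000 m) — physically correct even
though equal-area weighting would be indistinguishable at the printed
precision — and convert Mg C ha^−1^ to Pg C.

Deficit maps are *not* clipped at zero: negative values mark pixels
where regrowth has carried observed stocks above the modelled
potential.

The year-level retraining design has a useful testable consequence: the
reconstruction never reads observations outside the intact mask, so
AGB~pot~ is bit-invariant to any perturbation of disturbed-pixel
observations. The test suite asserts exactly that.

## Statistics

Trends are ordinary least squares of a series on the year, reported
with the Pearson correlation and its two-sided t-test p-value
(`stats::cor.test`); a zero-variance series is reported as a flagged
degenerate result in map contexts and an error in scalar contexts.
Detrending takes OLS residuals (idempotent, mean zero to 10^−10^).
The ENSO winter composite averages the four bimonthly index values
Dec/Jan–Mar/Apr, with Dec/Jan assigned to the year containing the
January: the boreal-winter ENSO peak precedes and overlaps the growing
season that shapes that calendar year's stocks. Climate sensitivity is
the correlation between the winter composite and the *detrended* annual
increments of potential (or observed) totals over the disturbed zone.

Per-pixel temporal correlation maps (e.g. primary-land fraction vs
deficit) use a two-sided test at α = 0.05 with **no multiple-testing
correction** — each pixel is read as its own test, a deliberately
liberal convention appropriate for descriptive significance hatching,
not for family-wise inference. Spatial correlations across pixels are
unweighted; area weighting is a documented alternative that makes no
qualitative difference at these latitudes.

## The synthetic world

Real inputs (satellite AGB percentile maps, interpolated climatology,
intact-forest masks, ENSO indices, land-use series) cannot be bundled,
so the generator emits worlds with the same statistical skeleton, plus
the ground truth needed for recovery tests:

* a static monthly climatology built from smooth spatially correlated
  surfaces (sums of random cosine waves) with a seasonal cycle and
  independent monthly anomalies; the base surfaces carry enough
  fine-scale structure (up to four cycles per domain) that the intact
  zone samples the full climate envelope of the basin — real
  quarter-degree climatologies have comparable orographic detail, and a
  space-for-time model has nothing to learn the dry tail from without
  it;
* a true potential surface — linear terms in the annual-mean climate
  layers plus a saturating precipitation response and a
  temperature-moisture interaction — chosen so a model-tree ensemble
  can approximate it well but a single global linear model cannot;
* an AR(1) bimonthly ENSO index whose winter composite shifts each
  year's potential by `enso_coupling` (default −2 Mg C ha^−1^ per index
  unit: warm phases depress the potential), plus independent
  interannual noise (sd 1 Mg C ha^−1^);
* a clearing process with spatially clustered probability (a smooth
  propensity field plus a south-east gradient, mimicking an arc of
  deforestation), burnt in from 1960 so the first observed year already
  carries a realistic deficit (~20% of potential, rising through the
  record); cleared pixels lose a uniform 40–90% of remaining biomass
  and recover exponentially at `regrowth_rate` (default 3% yr^−1^);
* observations equal to potential × (1 − deficit fraction) plus
  Gaussian noise (sd 2 Mg C ha^−1^), bracketed symmetrically by
  5th/95th maps at ±8% (the relative half-width implied by published
  confidence ranges); open-water pixels keep one constant value across
  all years;
* companion series: a stress index anti-correlated with the winter
  composite, a clearing-rate series proportional to the carbon newly
  cleared each year, and per-pixel primary-land fractions that decline
  only where clearing occurred.

Defaults are the package's study conditions: a 40 × 40 cell 0.25°
domain, years 1993–2012, intact fraction 0.55 of the basin, 2% open
water. They were fixed from the published setting (grid resolution,
period, intact fraction, deficit magnitude and trajectory, observation
spread) or, where nothing is published, from what is ecologically
plausible — and not revisited afterwards.

What the generator does **not** emulate: realistic geography or
seasonality phase, radiative-transfer/VOD observation physics,
spatially structured observation error, CO~2~ fertilisation (implicitly
folded into the intact-forest series, as in the real analysis), or
climate trends in the climatology itself (static by construction, as
interpolated climatological normals are). Passing recovery tests on
these worlds therefore demonstrates that the machinery is correct and
well-calibrated under the stated assumptions — not that those
assumptions hold for any particular satellite product.

## Validation semantics

`holdout_validate()` splits the intact mask 50/50 at random, trains on
one half and scores the other. *Integrated* bias is the bias of the
area-weighted holdout total; *local mean relative* bias averages
per-pixel relative errors, restricted to pixels observed above
10 Mg C ha^−1^ — near-zero denominators would otherwise dominate the
mean, a case the bias definitions do not otherwise address. Both
metrics recompute exactly from the stored residual field.

## Problem sizes and numerical conventions

Routine test and example runs use the default 40 × 40 world with 100
trees (a full three-level, twenty-year ensemble is 60 forest fits and
runs in minutes on one core) or a 20 × 20, single-climate-variable
world where only mechanics are at stake; 1,000 trees reproduce the
full-scale configuration at proportional cost. Missing values are a
single NA sentinel excluded from sums and regressions, never treated as
zero. Latitude ordering is canonicalised south-to-north at the I/O
boundary; raster files are plain-text CSV with a metadata header,
written at 17 significant digits so a write/read cycle is bit-exact.
Aggregation tolerances (10^−12^ relative) reflect float summation
order, which the implementation keeps fixed.

## Known limitations

* The space-for-time assumption treats intact pixels as exactly at
  potential; small-scale disturbance inside "intact" areas biases the
  ceiling low by whatever that disturbance removes.
* Leaves extrapolate linearly only within their clamped range; where
  the disturbed zone's climate lies far outside the intact envelope,
  reconstructed potential saturates at the envelope edge and the
  deficit is correspondingly conservative.
* Percentile levels are processed as three independent pipelines; the
  resulting band is an uncertainty *envelope*, not a calibrated
  posterior interval.
* Significance maps are uncorrected for multiple testing by design;
  treat them as descriptive.

```{r example, eval = FALSE}
# A complete synthetic reproduction, written to `out/`:
res <- reproduce_synthetic(seed = 1, outdir = "out", n_trees = 100)
autoplot(res$run$deficit_table)
```
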