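---
title: "Modelling venom enzymatic phenotypes from bioclimatic predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling venom enzymatic phenotypes from bioclimatic predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomclim)
```

## The scientific problem

Snake venoms are variable traits: within one species, enzymatic activities
such as phospholipase A~2~ (PLA~2~), proteolysis and L-amino acid oxidase
(LAAO) can differ by an order of magnitude between populations. Because
snakes are ectotherms, climate is a plausible driver of part of that
variation. The package operationalises one way of asking the question:
regress per-sample enzyme activities on summaries of the local climate,
keep only models that survive a battery of specification checks, verify
that the surviving model is not an artefact of spatial structure, and then
use it to predict the phenotype everywhere the climate is known.

The pipeline is deliberately modest in its claims. A linear model of seven
climate summaries cannot capture diet, venom-gene copy number or local
adaptation; adjusted R² values in the 0.1–0.5 range are the realistic
outcome, and the diagnostic gates exist precisely to stop over-reading
models of that strength.

## Bioclimatic predictors

Seven indices summarise a 12-month climatology of minimum, maximum and
mean temperature (°C) and precipitation (mm): annual mean temperature
(AMT), temperature annual range (TAR), annual mean diurnal temperature
range (AMDTR), isothermality (I = AMDTR/TAR × 100), temperature
seasonality (TS = 100·SD(Tavg)/(AMT + 273.15)), annual precipitation
(APN) and precipitation seasonality (PS = 100·SD(PPT)/(1 + APN/12)).
Only annual summaries are used: indices tied to a particular month or
quarter are excluded because a sample gives one venom phenotype per snake,
not a seasonal series.

Two conventions needed a decision:

* **SD denominator.** The seasonality indices divide a standard deviation
  of 12 monthly values. The default is the sample SD (n−1), the convention
  of the statistical environments these analyses are usually run in; the
  WorldClim rasters use the population SD. A `sd_denominator` switch
  selects between them.
* **TS form.** TS is implemented as the printed coefficient-of-variation
  form above; WorldClim's BIO4 is SD×100 with no kelvin denominator. A
  `mode = "worldclim"` compatibility flag reproduces BIO4, because studies
  frequently mix hand-computed and downloaded layers.

`compute_bioclim()` works per site; `bioclim_stack()` applies the same
arithmetic per pixel over aligned raster stacks and is tested to agree
exactly with per-site application. A pixel missing any month in any
variable is NoData in all seven outputs. Isothermality is undefined (NA)
when TAR = 0.

## Rasters

No reprojection or resampling is performed anywhere: rasters are accepted
only as mutually aligned, north-up WGS84 grids with square pixels, and
clipping (`clip_to_bbox()`) snaps outward to pixel edges. Point sampling
(`extract_at_points()`) takes the containing pixel — no interpolation —
under a half-open convention (`[left, right)` × `(top, bottom]`) so a
point on a shared edge belongs to exactly one pixel. Files are ESRI ASCII
grids written with 17 significant digits, so write→read round-trips are
bit-exact. The subcontinental clip window used for national maps is
68.1–97.4 °E, 6.74–35.7 °N (`india_bbox()`).

## Assay reduction

Raw readouts become regression inputs in three steps. A standard curve
(known analyte amounts vs absorbance) is fitted by OLS; a kinetic series
is reduced to a rate as the OLS slope of absorbance against time — using
all time points rather than a first-minus-last difference, since the whole
series is measured — and the specific activity is
rate (AU/min) ÷ curve slope (AU/nmol) ÷ venom mass (mg), in nmol/min/mg.
A negative fitted rate is clipped to zero and flagged rather than
propagated. Proteolytic readouts stay on their relative scale (percent of
a purified protease standard); values above 100% are allowed and flagged.
No blank subtraction is applied by default. Replicates are averaged before
regression; the replicate SD is carried for reporting only. One-way ANOVA
(`oneway_anova()`) compares within- and between-group variability of
replicate assays; with zero within-group variance and unequal means it
reports F = ∞, p = 0 explicitly instead of NaN.

## The model grid

For each response transform τ ∈ {identity, ln, √, 1/y} the full multiple
regression on the candidate predictors is fitted, refined and gated:

* **Transforms** apply to the response only. Domain violations (ln or 1/y
  of a zero activity) are hard errors when fitting a single model — a
  silent offset would change what the model means — but inside the grid
  such a cell is marked unavailable rather than aborting the other cells.
* **Stepwise rule.** Backward elimination drops the predictor with the
  largest coefficient p-value above α = 0.05, one per refit, stopping when
  all remaining predictors are significant; ties break by predictor order.
  An optional `protect_adj_r2` mode refuses any drop that lowers adjusted
  R². It is off by default for a statistical reason: dropping a predictor
  lowers adjusted R² exactly when its |t| > 1, so the guard would retain
  every non-significant predictor with 1 < |t| < t~crit~ — about a quarter
  of pure-noise predictors — and the procedure could then never reliably
  eliminate noise variables. With the default rule, a noise predictor
  survives with probability ≈ α.
* **Fit statistics.** Adjusted R² = 1 − (1−R²)(n−1)/(n−k−1); AIC uses the
  Gaussian profile-likelihood convention n·ln(RSS/n) + 2(k+2). Because an
  AIC on a transformed response includes no Jacobian term, AIC is
  comparable only within a transform; cross-transform downselection
  therefore uses adjusted R² plus the gates, never AIC.
* **Diagnostics.** Shapiro–Wilk on residuals (normality, N); Breusch–Pagan
  in the studentized (Koenker) form by default with the classic variant by
  flag (homoscedasticity, H); the Rainbow test with central fraction 0.5,
  observations ordered by fitted values (linearity, L); and VIFs with a
  pass threshold of 10 (multicollinearity, M). All gates use α = 0.05. A
  numerically perfect fit leaves Shapiro–Wilk and Rainbow undefined; those
  gates then pass with an explicit `degenerate` flag.
* **Downselection.** Among available cells whose refined model passes N, H
  and L, retains at least one predictor and has F-test p ≤ α, the highest
  adjusted R² wins. M reports but does not veto: the seven indices are
  climatologically coupled (AMT, TAR and AMDTR share the same underlying
  fields), so inflated VIFs are the norm rather than a disqualifier, and a
  model can be retained for prediction while its individual coefficients
  are read with caution. If no cell qualifies the card says so — "no
  significant model" is a legitimate scientific result.

## The spatial check

Samples collected along a climatic gradient are also spatially clustered,
so a significant climate coefficient could in principle be a disguised
spatial trend. `gwr_fit()` refits the model locally at every site with
Gaussian kernel weights w = exp(−d²/2b²) on inter-site distances in
degrees (the study extents here are small enough that the lon/lat metric
distortion is immaterial next to kernel-bandwidth uncertainty). The
bandwidth is chosen by cross-validation over a log-spaced grid, holding
out the entire *location* rather than the single sample: venoms pooled at
one site share coordinates, and ordinary leave-one-out would let a
sample's co-located replicates predict it, driving the bandwidth towards
zero. Local fits that become rank-deficient at small bandwidths are
flagged and excluded from the summary rather than failing the run. The
headline output is, per coefficient, the SD of the local estimates divided
by the global SE: ratios well below 1 mean the local fits just re-estimate
the global model and no spatial non-stationarity is in evidence. Note that
with strongly collinear predictors and small CV-chosen bandwidths the
local estimates can be noisy; the summary is a screen, not a test.

## Prediction maps

`predict_surface()` evaluates the fitted linear predictor at every valid
pixel of an aligned covariate stack and back-transforms to activity units.
Three choices matter:

* **Naive back-transformation.** exp, square or reciprocal without a
  retransformation (smearing) correction. For the ln transform this makes
  the map a conditional-median rather than conditional-mean surface —
  a known, documented caveat.
* **No clamping, explicit extrapolation mask.** A nationwide projection
  from a few dozen sampling locations inevitably extrapolates; predictions
  are not clipped to the observed activity range, but every pixel whose
  covariates fall outside the training range is marked in a companion 0/1
  mask layer so map readers can see where the model is interpolating.
* **NoData propagation.** A pixel missing any covariate is NoData in the
  map; a reciprocal of zero becomes NoData rather than ±∞.

The exported artefacts are the raster itself, a JSON sidecar with
min/mean/max and the per-row/per-column mean-activity profiles (the strips
drawn along map axes), the mask, and an optional blue-to-red PNG
rendering. The raster is the contract output; the rendering is a
convenience.

## The synthetic generator

`venom_scenario()` builds a complete, seeded study: smooth climate fields
(low-order spatial trend plus Gaussian bumps, seasonal cycles with
spatially varying amplitude so TS and PS span a realistic range,
tmax ≥ tavg ≥ tmin and ppt ≥ 0 enforced by construction), sampling sites,
and activities from a known linear truth. The default sampling design —
115 samples over 34 distinct locations — mirrors a realistic pooled field
campaign. Replicates share their location's coordinates exactly by
default, so unique-location counting is well defined; a `jitter` knob
(< 1 pixel) produces the nearby-pooled-sample variant instead.

The preset scenarios were fixed once, on climatological and assay
grounds, and each exists to exercise one failure mode:

* **basic** — identity scale, β = (AMT 3, PS 0.8) nmol/mg/min per unit,
  σ = 8, giving activities around 90–160 and R² near 0.5: a
  moderate-strength, well-specified baseline comparable to a strong
  observed protease model. The high-SNR variant used for support-recovery
  checks doubles the temperature effect (β = (6, 1)) so true-predictor
  t-statistics sit near 6–10.
* **lognormal** — truth on the log scale with enough signal
  (β = (0.35, 0.07), σ = 0.35) that activities span roughly two orders of
  magnitude, as LAAO activities do in real venom panels. The spread is
  what makes the four transforms distinguishable: identity/√ cells then
  fail normality or homoscedasticity while the ln cell is well specified.
* **hetero** — error SD proportional to APN, which is *in* the model:
  the Breusch–Pagan auxiliary regression sees the driving covariate, the
  configuration its power is defined against. 200 singleton sites.
* **collinear** — the diurnal-range field is generated from the
  annual-temperature field, making AMT/TAR/AMDTR near-collinear with
  full-model VIFs in the hundreds, reproducing the realistic
  multicollinearity failure mode.
* **spatial** — exponential error correlation (range 2°); with
  `beta_east`, a spatially varying slope for GWR cluster checks.

Domain-invalid noise draws (a negative activity under the identity
transform) are redrawn per sample; more than 10% redraws triggers a
warning that the scenario and transform are inconsistent.

What the generator does *not* emulate: real Indian climatology, monsoon
asymmetry, coastal gradients, or biotic drivers (diet, ontogeny). Passing
tests therefore demonstrate that the statistical machinery recovers what
it is pointed at under its own assumptions — not that climate explains any
particular real venom dataset.

## Numerical choices and problem sizes

Alignment comparisons use a 1e-12 relative tolerance; clip-window
arithmetic nudges by 1e-9 pixel before floor/ceiling so box edges that
coincide with pixel edges are not split by floating-point error. Stepwise
ties break by column order; grid downselection ties break by transform
order. The test-suite problem sizes — 1,000 random instances for the
closed-form oracles, 2,000 replicates at n = 200 for gate calibration,
500 datasets at n = 115 for coverage, 300 for support recovery, 20 model
grids for transform selection — were chosen to hold the Monte-Carlo error
of each checked proportion near or below one percentage point while the
whole suite stays interactive (under a minute).

## Known limitations

* Coefficients of collinear predictor sets are individually unstable;
  the pipeline reports VIFs but by design does not prevent a collinear
  model from being selected.
* The stepwise-selected model inherits all the usual post-selection
  inference caveats; reported p-values are not selection-adjusted.
* GWR here is a screen for non-stationarity, not a spatial error model;
  strongly autocorrelated residuals would require an explicit spatial
  regression, which is out of scope.
* Back-transformed maps carry retransformation bias (see above) and are
  only as good as the covariate rasters' alignment with the training
  climatology period.
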