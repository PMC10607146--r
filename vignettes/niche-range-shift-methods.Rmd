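---
title: "Methods: quantifying niche and range shifts of invasive vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying niche and range shifts of invasive vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vectorshift` quantifies how far the realized niche and the potential range
of an invasive species have shifted between its native and introduced
populations. The workflow was designed around the comparative biology of
*Aedes aegypti* and *Ae. albopictus*, but every stage operates on generic
inputs: occurrence records with population labels, and gridded
environmental predictors. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
simulation-based validation does and does not establish.

## The niche-shift model

Occurrence records of both populations are projected into a two-dimensional
environmental space: predictors are standardized over the pooled background
(all cells available to either population) and the first two axes of a
correlation-matrix PCA define the space (`pca_env()`). Following the COUE
scheme (centroid shift / overlap / unfilling / expansion), each
population's occurrence density is estimated on an `R x R` grid spanning
the pooled background scores with a Gaussian product kernel
(`density_grid()`, default `R = 100`), and the background availability is
estimated the same way.

The decomposition (`coue_indices()`) is computed on occupied cells:

* expansion `E` — introduced density mass in cells the native population
  does not occupy, as a fraction of total introduced mass;
* stability `S = 1 - E`;
* unfilling `U` — native mass in cells the introduced population does not
  occupy, as a fraction of total native mass.

`E + S = 1` holds exactly by construction; `U` is a fraction of the native
niche. By default the computation is restricted to analog environments
(cells where both backgrounds have positive density), since comparing
occupancy in environments only one population could ever reach conflates
availability with choice. No additional marginal-climate quantile trimming
is applied.

Two scalar indices summarize the decomposition with the introduced niche
breadth normalized to `IB = S + E = 1` and the native breadth `NB = S + U`
in the same units:

* breadth ratio `BR = IB / NB = 1 / (S + U)` — above 1 the introduced
  niche is the wider one;
* similarity index `SI = 2S / (IB + NB) = 2S / (1 + S + U)` — above 0.5
  the niches occupy similar positions.

This mixed-unit arithmetic (inserting `U`, a native-niche fraction,
directly into `S + U`) is deliberate: it is the composition that
reproduces every published (BR, SI) pair from the corresponding published
(E, S, U) triples, so it is adopted as the reference behaviour. The niche
is called *not conserved* only when both `SI < 0.5` and `BR > 1`
(`conservatism_verdict()`).

Niche overlap is Schoener's `D = 1 - 0.5 * sum(|z1 - z2|)` on occupancy
grids normalized to unit mass. Two permutation tests accompany it: the
equivalency test pools and re-splits the occurrences (alternative: lower
equivalency than random), and the similarity test re-centres the second
niche uniformly within its own background envelope (alternative: more
similar than random). Both use the `(r + 1) / (n + 1)` rank p-value.

### Numerical choices in the density grids

* **Bandwidth.** Normal-reference (Silverman) rule per axis
  (`stats::bw.nrd0`) on the occurrence scores; configurable. The rule is a
  documented default — the reference analyses in the literature rarely
  state their bandwidth.
* **Occupancy support.** A Gaussian kernel is positive everywhere, so some
  cutoff must define "unoccupied". Cells below `z_thresh` (default 0.05)
  times the maximum density are treated as unoccupied, and background
  cells below the same fraction of the background maximum as unavailable.
  The 5% default mirrors the 5%-of-maximum suitability cutoff used to
  delimit a virtual species' true niche, which makes the estimated and
  true COUE fractions directly comparable. Raising it shrinks every
  niche; lowering it towards zero drives `E` and `U` to 0 because kernel
  tails overlap everywhere.
* **Degenerate inputs.** Bandwidths are floored at half a grid-cell
  spacing so that point masses (all records identical) still produce a
  density; densities are renormalized to unit mass after the support
  cutoff.

## The range-shift model

Binary potential ranges come from ensemble species distribution models.
Presences are complemented with uniformly drawn pseudo-absences (as many
as the presences when there are more than 1000 presences, else 1000; three
independent replicates), and nine algorithms are fitted behind one plugin
contract (`fit_algorithm()`): GLM, classification tree, neural network,
flexible discriminant analysis, adaptive spline regression, gradient
boosting, random forest, a maxnet-style penalized logistic regression
standing for maximum entropy, and a native surface range envelope (score 1
inside the presence quantile box `[q, 1 - q]`, default `q = 0.025`).

Evaluation uses stratified 70/30 splits repeated five times per
pseudo-absence replicate: AUC by the Mann-Whitney rank statistic (ties
half) and TSS as the maximum of sensitivity + specificity - 1 over all
observed score thresholds. Evaluations are averaged per algorithm *before*
the inclusion rule (AUC > 0.8 or TSS > 0.6) and the TSS-proportional
weighting — the combination order is a design choice; averaging first
keeps one weight per algorithm and makes the inclusion rule operate on the
algorithm's central tendency rather than its luckiest split. Final member
models are fitted on the first replicate's full table. The ensemble
surface is binarized at the smallest observed score maximizing
sensitivity + specificity (ties to the smallest qualifying score, so the
binary range is the most inclusive of the equally good options).

Null models replace the training presences with uniformly random domain
cells (matching 70% of the real presence count), keep the pseudo-absences,
and evaluate on the held-out 30% of real presences; `p = (r + 1)/(n + 1)`.
A flexible learner (random forest) is the recommended algorithm here: a
misspecified parametric null (e.g. a linear-logit GLM on a unimodal niche)
depresses the real model's AUC more than the nulls' and wastes power.

Overlaying the two binary maps classifies every cell as expansion
(introduced only), stability (both), unfilling (native only) or absent;
areas use the spherical-zone formula with R = 6371 km
(`cell_area_km2()`), so latitude does not bias the indices. With
`PRI = RE + RS` and `PRN = RS + RU`:

* range ratio index `RRI = PRI / PRN`,
* range similarity index `RSI = 2 RS / (PRI + PRN)`,
* invasion rate ratio `(RE_a / duration_a) / (RE_b / duration_b)` — the
  invasion durations are explicit arguments because published invasion
  histories are ranges ("300-400 years" vs "30-40 years"), not points;
  the conventional comparison uses their 10:1 ratio.

## Occurrence processing

Cleaning follows the archive-processing order: deduplicate (one record
per (lon, lat, population) key rounded to 4 decimals, about 11 m), drop
records whose coordinate uncertainty exceeds 5 km (strictly "over";
records with *missing* uncertainty are retained, since absent metadata
cannot exceed a threshold — the retained count is reported for auditing),
then spatially rarefy with a 5-km great-circle radius. Thinning is a
greedy pass in seed-shuffled order: a record is kept iff it lies at least
the radius from every previously kept record, which guarantees the
min-distance invariant and is reproducible. Rarefaction is applied per
population by default — native and introduced records are thinned
separately — because cross-population interference would couple the two
samples the later stages treat as independent. Distances are haversine on
a 6371-km sphere; the sub-0.5% ellipsoidal error is immaterial at 5-km
scale. Population splitting uses boundary-inclusive ray-casting
point-in-polygon against native-region polygons; pre-labelled records keep
their labels (conflicts produce a warning).

## Bioclimatic variables

`compute_bioclim()` implements the 19 standard bioclimatic summaries from
monthly minimum/maximum temperature and precipitation grids, with the
WorldClim conventions: monthly mean temperature is `(tmin + tmax)/2`
unless an explicit mean is supplied; Bio4 and Bio15 use the sample (n-1)
standard deviation; Bio15 uses the `1 + mean` denominator; quarters are
all 12 cyclic consecutive 3-month windows (Dec-Jan-Feb allowed) with ties
broken by the earliest window; Bio3 is set to missing where the annual
range is zero. Resampling between grids (`resample_to_grid()`) is
bilinear for continuous layers and nearest-neighbour for categorical or
fractional ones.

## Predictor selection

Permutation importance (`variable_importance()`) scores each predictor as
`1 - cor(pred, pred_permuted)` averaged over shuffles, clamped to
`[0, 1]`; a predictor the model ignores scores exactly 0. Collinearity
pruning (`prune_collinear()`) repeatedly finds the pair with the largest
`|r| > 0.7` and drops its lower-importance member (ties: the
lexicographically later name), until no strong pair remains. Worst-first
ordering makes the procedure deterministic and removes the most redundant
information first. Correlations are computed on predictor values at
presence plus background cells — the modelling domain — rather than all
land cells.

## The virtual-species simulator

`generate_landscape()` builds layers as a deterministic linear gradient
(10 units across the grid; orientation varies by layer) plus
moving-average-smoothed Gaussian white noise — a simple, dependency-free
way to get spatial autocorrelation, not a full Gaussian random field.
`generate_monthly_climate()` drives monthly mean temperature with a
sinusoid around a per-cell annual mean (coldest month January, northern
convention), a fixed diurnal half-range (default 5 °C), and distributes a
per-cell annual precipitation total (default 1200 mm) over 12 nonnegative
monthly weights. A virtual species responds to each layer with an
independent Gaussian: `s = scale * exp(-0.5 * sum(((e - mu)/sigma)^2))`.
Records are drawn cell-proportionally to suitability and jittered
uniformly within the cell so deduplication and thinning operate on
non-degenerate coordinates.

The true COUE fractions of a species pair (`true_coue()`) binarize each
true suitability surface at 5% of its maximum (configurable) and count
cells. The Gaussian-response niche is a stand-in: no published ground
truth exists for the real species' niches, so parameter recovery is
validated against this synthetic truth only.

**What passing the simulation tests shows — and what it does not.** The
validation suite establishes that, on landscapes with smooth gradients and
Gaussian niches: an unshifted species pair is reported as unshifted
(E < 0.05, U < 0.10, SI > 0.9 at 2000 records per population), estimated
expansion increases monotonically with the true niche separation, and a
strong-signal species yields ensemble cross-validated AUC above 0.8 with
null-model p at its floor. Real mosquito data differ in ways the simulator
does not emulate: spatially biased sampling, non-Gaussian and interacting
niche responses, dispersal limitation, and the covariance structure of
real climate and land-use layers. Estimated E and U are also
conservative at small sample sizes (a few hundred records per
population), because kernel support shrinks with n.

## Problem sizes used in the tests

The validation suite uses a 60 x 60-cell landscape with three layers and
2000 records per population (three seeds) for the recovery checks, and a
50 x 50-cell landscape with 400 presences, three pseudo-absence
replicates, nine algorithms and five CV repeats for the ensemble checks —
sizes at which the estimators are demonstrably stable while the whole
suite stays quick to run. The analysis scripts under `analysis/` use a
60 x 60 landscape with 400 native / 1500 introduced records per species.
The acceptance script recomputes the published index values from the
published (E, S, U) and (RE, RS, RU) components; those are
three-component inputs, so it runs in well under a second.

## Known limitations

* No geospatial raster I/O: layers live as matrices plus a grid spec and
  are exchanged as gridded CSV text; GeoTIFF import/export would need a
  raster package.
* The environmental space is fixed at two PCA axes, as in the reference
  workflow; niches that separate only on axis 3 and beyond are invisible.
* The similarity test shifts niches rigidly within the background
  bounding box; it does not resample occupancy shapes.
* Pseudo-absence sampling is uniform over the domain mask; no
  target-group or bias-corrected sampling.
* `E`/`U` depend on the occupancy support cutoff; comparisons should use
  one cutoff throughout (the default 0.05 everywhere).
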