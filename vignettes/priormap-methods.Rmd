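---
title: "Models and methods behind priormap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind priormap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priormap)
```

`priormap` combines two independent views of where biodiversity lives on a
landscape — a presence-based species distribution model and a land-use-based
habitat-quality model — and confronts their agreement with protected-area
(PA) boundaries to map conservation priorities and gaps. This vignette
explains each model, its assumptions and tunable parameters, the numerical
choices made where the design was genuinely open, and what the synthetic
landscape generator does and does not emulate.

## Data model

All layers share one `grid_spec()`: an equal-area projected grid with cell
(1,1) at the top-left and the cell center at
`origin + ((col − 0.5), −(row − 0.5))·cell_size`. Every point-in-cell and
distance computation uses cell centers — one unambiguous rule for
rasterization, buffering and threat kernels alike. Layers on mismatched
grids are a hard error, never a silent resample; explicit resampling (by
nearest neighbour for classes, bilinear for continuous fields) belongs to
data preparation, not to the analysis, which is also why no geostatistical
interpolation is performed inside the package. Rasters are read and written
as plain-text ESRI ASCII grids and polygons as GeoJSON, formats every GIS
understands; nodata cells are `NA` internally and the file sentinel only on
disk. Area accounting is `cell count × cell_size²`, with percentages
rounded half away from zero to two decimals (with a square-root-of-epsilon
nudge so decimal halves like 2.675 round upward despite binary floating
point).

## Occurrence thinning and covariate decorrelation

Occurrence records arrive with duplicates and spatial clumping that bias
presence-background models. `thin_occurrences()` removes exact duplicate
same-species locations first, then makes one greedy pass in input order,
keeping a record only while fewer than `max_per_neighborhood` (default 2)
already-kept records of that species lie within `min_dist` (e.g. 1 km).
The scan order is deliberately the file order: no ordering is canonical for
this rule, and fixing input order makes the filter deterministic and
auditable. Thinning is per species by default, since records of different
species are not pseudo-replicates of one another; a joint mode exists for
multi-species survey designs.

`select_variables()` resolves collinearity by repeatedly finding the pair
of covariates with the largest |Pearson r| above the threshold (default
0.8) and dropping its lower-scored member, logging every drop with its
partner and correlation. Any per-variable ranking can serve as the score;
the natural choice is the univariate maxent training gain (the jackknife
"only this variable" gain), since a model-contribution ranking is not
available before a model exists. Score ties keep the earlier variable in
input order. Correlations are computed over the cells valid in every
layer, sampled down to 100,000 cells with a fixed seed (42) when the grid
is larger, purely to bound computation.

## The maximum-entropy model

The model estimates the distribution of a species over landscape cells as
the Gibbs density `p(x) ∝ exp(λ·f(x))` that maximizes the L1-penalized
training gain

```
gain(λ) = mean_presence λ·f(x) − log mean_background exp(λ·f(x)) − rm · Σ_j β_j |λ_j|
```

**Features.** Linear, quadratic and pairwise-product transforms of the
covariates — the classic "LQP" set. Covariates are standardized over the
background sample, and each feature column is standardized again so one
penalty scale is comparable across feature classes. Hinge and threshold
features are deliberately absent: LQP keeps the objective smooth apart
from the L1 kinks, the feature count quadratic in the covariates, and the
fit fully reproducible, at the cost of less flexible response curves.

**Regularization.** `β_j = sd_j(presence features)/√m` — the classic
variance-based maxent scaling, under which the penalty approximates a
confidence interval on each feature's presence mean — times the
regularization multiplier `rm` (default 1.1, the value used throughout the
validation protocol). A floor of 0.05 on the presence standard deviation
keeps near-constant features from escaping the penalty.

**Optimizer.** Monotone accelerated proximal gradient (FISTA with a
decrease safeguard): each iteration proposes an accelerated step and falls
back to a plain proximal step whenever the accelerated one would increase
the penalized objective, so the objective trace is non-increasing by
construction — a property the test suite asserts. Backtracking line search
handles the step size; convergence is declared at a relative objective
change below 1e-6 (maximum 500 iterations, non-convergence is an error
carrying the trace). The problem is convex, so the optimum is unique up to
features with ties in the penalty.

**Output scale.** The raw Gibbs density is normalized over the background
sample; the reported suitability is the conventional bounded transform
`c·raw/(1 + c·raw)` with `c = exp(H)`, `H` the entropy of the fitted
background distribution. It is strictly increasing in the linear
predictor, lies in [0, 1], and places a "typical" cell near 0.5 — the
scale presupposed by fixed suitability class cut-offs.

**Validation.** `evaluate_maxent()` repeats the protocol of four random
75/25 presence splits, refitting on each training part and scoring
rank-based AUC (Mann–Whitney; ties count half) against the full
background. Four *independent* splits are used rather than 4-fold
cross-validation — the protocol names both a fixed split proportion and a
replicate count, which independent splits satisfy simultaneously — and a
`kfold` flag provides disjoint folds when wanted. Three importance
measures are reported per covariate: *permutation importance* (AUC drop
after permuting one covariate across evaluation cells, normalized to
100%), which is solver-invariant and therefore the measure the acceptance
checks rely on; *percent contribution* (the share of objective improvement
credited to each feature along the optimization path, products crediting
half to each parent), which — as in the original maxent software — depends
on the optimization path and is documented as such; and *jackknife gains*
(only-this-variable and without-this-variable refits).

## Habitat quality

Each threat source `r` has a weight `W_r`, a maximum influence distance
`d_max` and a decay kind. The shipped parameter table is the published
one: field 5 km/0.3/linear, towns 12/1.0/exponential, villages
10/0.9/exponential, roads 10/0.8/linear, railways 8/0.7/linear, mines
9/0.8/exponential ("index" in the source table is read as exponential —
the only two printed decay formulas are the linear and exponential ones).
Influence decays as `1 − d/d_max` (linear) or `exp(−2.99·d/d_max)`
(exponential, ≈5% at `d_max`), and both kernels are truncated to zero
beyond `d_max` so every threat has compact support; the exponential form
alone never reaches zero, which would make the double sum over threat
cells unbounded in extent.

Degradation is the raw weighted double sum
`D_x = Σ_r Σ_y (W_r/ΣW_r)·r_y·i_rxy·β_x·S_jr` — weights enter only through
their normalized form, so rescaling all weights changes nothing.
Computation is by per-threat kernel accumulation (each threat cell adds a
precomputed decay patch), which equals the naive quadruple loop exactly,
not approximately; the suite verifies equality to 1e-10 on grids up to
30×30. Quality is the half-saturation transform
`Q = H_j(1 − D^z/(D^z + k^z))` with defaults `z = 2.5`, `k = 0.5` — the
de-facto standards for this model family, since the source leaves both
numerically unspecified. Note that `D` is an unnormalized sum whose
magnitude grows with threat density, so on threat-dense landscapes `D ≫ k`
and absolute `Q` values are small; this is immaterial downstream because
hotspot binarization is rank-based (top quartile of valid cells by
default), which is invariant to the scale of `Q`. For absolute quality
maps, `k` should be set near the median positive `D` of the landscape;
both constants are configurable. Accessibility `β_x` defaults to 1
everywhere (no accessibility data in scope), and classes with `H_j = 0`
report their degradation but have zero quality by construction.

The binarization of `Q` into "habitat hotspots" is not stated in the
source at all; the default here is the top 25% of valid cells, with a
fixed-cut alternative, and the choice is surfaced as an explicit argument
rather than buried.

## Gap analysis

Two binarizations coexist deliberately. Per-species suitability maps are
binarized at the species' 10% training-presence threshold (the value below
which the lowest 10% of training presences fall — self-calibrating and
conservative), and the union across species defines the species-model
hotspot mask. The aggregated richness surface is additionally classified
with the fixed bounds 0.25/0.55/0.90 into unsuitable / less / moderately /
highly suitable, with lower boundaries belonging to the class above and
the top class strictly above 0.90. The fixed bounds describe the richness
map for area accounting; the training-presence rule decides hotspot
participation, where a fixed cut on an aggregated, renormalized surface
would be arbitrary.

The overlay assigns each cell one of eight categories: outside PAs —
habitat-quality-only ("priority"), species-model-only ("key priority"),
both ("priority outside core"); the same three tiers inside PAs; plus
over-protected (inside a PA, flagged by neither model) and background.
The categories partition the valid grid exactly, and the core zone is by
construction the model intersection. Because no single agreement
definition is standard, `model_agreement()` reports Jaccard, the overlap
coefficient and the intersection's share of each map side by side. Per-PA
action bins cut the inside-PA priority proportion at 25% and 75%, with
boundary values assigned to the higher bin (interval notation in the
source overlaps at the boundaries; a rule had to be fixed and is
documented here).

## The synthetic landscape generator

The generator exists so the pipeline's statistical claims can be tested
against constructed truth. Its defaults are the study conditions of the
validation protocol: a 100×100 grid of 100-m cells (a 10×10 km landscape —
every oracle and end-to-end test runs in seconds; regional 30-m
applications are a rescaling of `cell_size`, nothing in the code depends
on the desk scale), four standardized covariate fields with a Gaussian
autocorrelation range of 8 cells, species with a two-covariate signal of
weights 2 and 1 and 300 presences sampled from the implied Gibbs density,
and PAs covering exactly 60% of the true hotspot cells. Covariate fields
are kernel-smoothed white noise (FFT convolution on the torus) — enough to
give realistic spatial structure, though not a full geostatistical
simulation with a specified variogram. The land-use mosaic
quantile-thresholds a latent field into the requested class mixture, then
draws one-cell-wide road and railway random-walk lines and small mine
patches on top. PA placement seeds squares on hotspot cells and tops up
with single-cell reserves so the covered fraction is met exactly, making
truth gap areas exact counts.

What the generator does *not* emulate: real covariate semantics (no
seasonality, no climate gradients), observation bias in occurrences
(records are unbiased draws from the true density), irregular PA shapes,
and class-dependent covariate structure. Passing tests therefore
demonstrate that the algorithms recover what they are mathematically
supposed to recover under the model's own assumptions — not that any
particular real landscape satisfies those assumptions.

## Problem sizes and numerical conventions

The validation protocol fits 20 simulated species (300 presences, the
full 10,000-cell background, RM 1.1, four 75/25 replicates each) and
requires the median test AUC to reach 0.80 and the true signal covariate
to top permutation importance in at least 16 of 20 species; gap recovery
runs the complete pipeline on five seeded landscapes with PAs covering
60% of true hotspots and requires the mean reported gap within 15% of the
constructed truth. Oracle-equivalence checks run on grids up to 50×50
(geometry), 30×30 (degradation) and n = 200 (AUC pairs). Degenerate
inputs are handled explicitly: constant covariate layers correlate at 0
with a warning flag, constant suitability maps normalize to zero with a
warning, degenerate quality maps yield no hotspots, empty polygon sets
rasterize to zeros with a warning, and PAs rasterizing to no cell are
flagged and left unbinned.

## Known limitations

Hinge/threshold features and multi-species joint models are out of scope,
as are reprojection, geodesic areas, habitat rarity/scarcity, future
land-use scenarios, and optimization-based reserve design with cost
layers. Percent contribution is path-dependent by nature; use permutation
importance for solver-independent rankings. The printed regional results
of real applications (areas of tens of thousands of km², AUCs averaged
over dozens of real species) depend on proprietary regional rasters and
survey records; the package reproduces their arithmetic identities and
the statistical behaviour of the methods, not the regional maps
themselves.
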