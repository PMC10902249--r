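---
title: "Methods: habitat projection for Southern Ocean mesopelagic fish"
author: "mesohab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat projection for Southern Ocean mesopelagic fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesohab)
```

## The problem

Mesopelagic fishes dominate Southern Ocean fish biomass and link
zooplankton (including Antarctic krill) to seabirds, seals and whales, yet
they are rarely weighed in marine protected-area (MPA) design. `mesohab`
implements, as a reusable and testable pipeline, the analysis chain used to
ask how their habitat will move under climate change and how well current
and proposed MPAs cover it:

1. clean and spatially rarefy presence-only occurrence records to one
   record per 1° grid cell;
2. fit an ensemble of three presence-background species distribution
   models (SDMs), evaluate them by repeated cross-validation, and project a
   habitat suitability index (HSI) for present and future climate
   scenarios across several Earth System Model (ESM) variants;
3. infer residual species-to-species associations with a latent-factor
   probit joint SDM;
4. convert HSI maps to binary habitat with a top-5% rule and quantify
   gain/loss/stability, regional area change and centroid latitude shifts
   on an equal-area basis;
5. identify community "important areas" (IAs) and report their coverage by
   current and negotiated protected areas.

Because real occurrence archives (GBIF/OBIS/KRILLBASE), CMIP5 climate
fields and CCAMLR MPA polygons cannot be bundled, every stage runs against
a synthetic data generator with known ground truth. All empirical
statements below are computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from external data.

## The synthetic study system

`makeEnvGrid()` builds a seven-variable present-day (1956–2005) stack on a
1° circumpolar grid south of 35° S (55 × 360 cells): sea-ice fraction (%),
SST (°C), sea-surface salinity, temperature and salinity at 200 m,
bathymetry (m) and primary productivity.

Design choices, made once:

* **SST field**: linear in latitude (`sstNorth = 12` °C at 35° S,
  `sstSlope = 0.45` °C per degree) plus a smooth zonal sine perturbation
  (amplitude 0.5 °C) and seeded Gaussian noise (SD 0.3 °C). Linearity is
  the simplest form with a recoverable poleward signal. The slope is set
  so the −1 °C isotherm sits near 64° S — in open ocean, roughly where the
  real seasonal ice edge lies — leaving a cold-water escape route south of
  the warm-edge species; a flatter gradient would pin such species against
  the synthetic continent and the poleward-shift dynamics of the real
  system could not be emulated. The linear field undershoots the physical
  freezing point at extreme latitudes; those cells are mostly land and the
  simplification is accepted.
* **Bathymetry** is fixed (no seed): a pole-centred continent whose edge
  undulates with longitude (±3° around 74° S), a 3°-wide shelf at −400 m,
  a 3° slope, and an abyssal bowl near −3800 m. This guarantees both shelf
  and open-ocean habitat, which the community structure needs. Land is
  `depth >= 0`, and that mask defines "terrestrial" records during
  cleaning — the only land definition the package carries.
* **Sea ice** follows a logistic front centred at 62° S (width 3°),
  clipped to [0, 100]. **Productivity** is a mid-latitude Gaussian ridge.
* **Scenarios**: `scenarioDelta()` holds additive change fields per
  variable. Defaults are CMIP5-scale Southern Ocean magnitudes (e.g. SST
  +0.6 °C for RCP4.5 short-term to +2.2 °C for RCP8.5 long-term, with ice
  declines of 4–15 percentage points). `applyScenario()` adds the delta,
  then a per-ESM seeded Gaussian perturbation (per-variable SDs, e.g.
  0.15 °C for SST), then clips ice. Zero delta with zero ESM amplitude
  reproduces the input bit for bit. `esmVariant()` applies the same
  perturbation machinery to the present period so that, as with the four
  CMIP5 ESMs, every period exists in four flavours.
* **Occurrences**: presence cells are drawn with probability proportional
  to a product-Gaussian niche suitability
  $s(x) = \exp\{-\sum_v w_v (x_v - \mu_v)^2 / 2\sigma_v^2\}$, jittered
  uniformly within the cell, with years uniform on 1955–2005 (the
  present-day window). Cells can repeat — rarefaction is a downstream
  responsibility, as with real survey data. The number of records per
  species is a free parameter (no archive count exists to match); the
  default 300 is in the range where the SDMs are comfortably identifiable
  on this grid.
* **The default community** has five temperature-led "lanternfish-like"
  species spanning optima 1–4 °C and four sea-ice-led "high-Antarctic"
  species (one with a shelf depth preference), plus an ice-edge krill
  analogue, mirroring the ecological contrast the analysis is about.

What the generator does **not** emulate: ocean fronts as sharp ecological
boundaries, interannual variability and monthly resolution, spatially
autocorrelated sampling bias, and observation error in coordinates. Tests
passing on this generator therefore demonstrate correctness of the
machinery and recoverability of niche signal — not that any particular
real-world percentage would be reproduced.

## Occurrence preparation

`filterRecords()` drops, in order: invalid/out-of-grid coordinates,
records before 1955, records north of 35° S, preserved specimens, and
records on land cells; each dropped record is counted under exactly one
reason. `dedupeAndRarefy()` removes exact duplicate rows first (so
duplicates cannot bias the mean), then collapses each cell's records to
one record at their arithmetic mean coordinates (longitudes averaged
circularly when a cluster spans the dateline) — mean coordinates are kept
rather than snapping to cell centers, an open choice documented here. The
full prep is idempotent and per-cell unique, both property-tested.

## The SDM ensemble

Three presence-background models are fitted on the seven covariates (none
are excluded for collinearity — the tree ensembles tolerate it and the
covariates are all biologically relevant):

* **RF**: a 500-tree probability random forest;
* **BRT**: stagewise boosted trees, learning rate 0.01, depth 3, up to
  1200 rounds with early stopping on a held-out 15% log-loss (patience
  30);
* **MAXENT-style**: an $\ell_1$-regularized logistic model on linear +
  quadratic features, penalty chosen by internal 5-fold cross-validation.
  The quadratic terms make a Gaussian niche exactly representable, and the
  fitted response is unimodal in the driving variable (tested).

Background points are sampled uniformly over non-presence ocean cells,
10 × the presence count by default (capped at the ocean-cell count),
following standard presence-background practice; no field convention
pins this quantity down, so it is a configuration value.

Evaluation is 10 independent stratified 70/30 splits. Per repetition and
algorithm we record AUC (rank-sum form, ties = ½) and maximum TSS over an
exhaustive threshold scan (midpoints of adjacent unique scores plus the
extremes; smallest maximizer on ties) — TSS needs a binarization
threshold, and the package adopts the common TSS-maximization convention. Variable importance is the permutation AUC-drop on the test split
(5 permutations per variable), floored at zero and normalized; a constant
column scores exactly zero.

Ensemble weights are the per-algorithm mean TSS clipped at zero and
normalized; projection maps are the cellwise convex combination of the
member maps, and cross-ESM "ensemble" maps are the unweighted cellwise
mean over ESM variants. Final projection models are refitted on all data;
cross-validation is used only for evaluation and weights.

## The joint species distribution model

Residual associations come from the latent-factor probit model
$y_{ij} \sim \text{Bernoulli}(\Phi(x_i^\top \beta_j + \lambda_j^\top z_i))$
with $z_i \sim N(0, I_q)$, fitted by a Gibbs sampler with
truncated-normal data augmentation and conjugate normal updates.
Defaults (all config-exposed): $q = 2$ factors, priors
$\beta \sim N(0, 10^2)$ and $\lambda \sim N(0, 1)$, 5000 iterations with
1000 burn-in and thinning 5, and 1000 subsampled ocean cells — a desk-scale
site count that is ample for correlation estimates.

Identification: $\Lambda$ is constrained lower-triangular; instead of
sampling the diagonal from truncated normals, columns are drawn
unconstrained and deterministically sign-flipped to a positive diagonal.
The reported quantity, $R = \text{cov2cor}(\Lambda\Lambda^\top + I)$, is
invariant to column sign flips, so this changes nothing downstream while
keeping the conditionals conjugate. With $q = 0$ the sampler collapses to
independent probit regressions and $R$ is exactly the identity (tested).

Significance uses the 99% highest-posterior-density interval — the
shortest contiguous window of sorted draws holding $\lceil 0.99 n \rceil$
draws, smallest start on ties — excluding zero. Cross-ESM averaging is the
entrywise mean of the per-ESM posterior-mean matrices; significance of the
average pools the post-burn-in $R$ draws of all four chains into one HPD
interval — the package's convention for combining evidence across ESM
variants.

## Habitat change on an equal-area basis

`binarizeTop5()` reads "top 5% of the habitat distribution" as the 95th
percentile rank rule: the top $\lceil 0.05 N \rceil$ valid cells are
suitable, the threshold is the minimum suitable HSI, and cells tied with
the threshold are included. The alternative fixed reading (HSI ≥ 0.95,
which coincides with the percentile rule only for uniformly distributed
HSI) is selectable via `rule = "fixed"`.

Instead of re-projecting rasters to a polar equal-area projection, all
area and centroid statistics use exact spherical cell areas,
$A = (\pi/180)\,\Delta\lambda\,R^2(\sin\varphi_2 - \sin\varphi_1)$ —
mathematically what any true equal-area projection preserves, without
resampling artifacts; latitude-band sums and the 35° S polar cap are
verified against closed forms to relative error < 1e-9. Change maps
partition valid cells into gain / loss / stability / never. Regional area
change splits the domain at the 0°/180° meridians (western half contains
the Antarctic Peninsula side, eastern half East Antarctica; the boundary
is configurable since no standard definition exists). Centroid shift is
the area-weighted mean suitable-cell latitude, future minus present;
negative is poleward.

## Protected-area overlap

Community IAs are the top-5% cells of the unweighted mean HSI over the
nine species; the krill analogue uses the same rule on its own map.
Polygons are rasterized by cell-center point-in-polygon (deterministic on
the 1° grid; fractional coverage is out of scope), with current status
taking precedence where polygons overlap, and the three-way coverage
partition (current / negotiated-excluding-current / outside) is
area-weighted (a cell-count variant is available by passing unit areas)
and always sums to 100%.

## Numerical and reproducibility choices

* Every stochastic step takes a seed; stage seeds are derived
  deterministically from one master seed, and identical configurations
  give bit-identical outputs (hash-verified manifests; wall-clock timing
  is written to a sidecar file so the manifest itself is reproducible).
* Degenerate inputs fail loudly: all-equal HSI maps, empty IA sets,
  all-zero niches, single-class training data, chains shorter than their
  burn-in.
* Longitude means are computed arithmetically when a cluster spans less
  than a half-circle (exact, hence idempotent prep) and circularly
  otherwise.

## Problem sizes

The shipped tests and the acceptance script use: 300 presences / 3000
background with 10 × 70/30 cross-validation for SDM recovery; 400 sites,
$J = 6$, $q = 2$, 5000 iterations for joint-model recovery; the full
55 × 360 grid for all map-level checks; and a reduced pipeline
configuration (three species plus the krill analogue, two ESM variants,
one scenario/period, short chains) for the end-to-end determinism check.
These sizes are the package's choices for a desk-scale demonstration; all
of them are configuration values that scale up unchanged.

## Known limitations

* The synthetic fields are smooth and the niches are exactly Gaussian, so
  SDM skill here is an upper bound on what messy real data would give.
* Associations estimated from *modelled* binary habitat inherit the SDMs'
  errors; as with the real analysis, residual correlation reflects shared
  unmeasured structure, not direct interaction.
* Presence-only ensembles give relative, not absolute, suitability; the
  top-5% rule makes results threshold-relative by construction.
* The pipeline's per-ESM weights and pooled-draw significance are
  reasonable conventions among several defensible ones; both are isolated
  behind configuration so alternatives can be swapped in.
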