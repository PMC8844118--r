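---
title: "Methods: quantifying climate-dataset version mismatch in habitat suitability models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying climate-dataset version mismatch in habitat suitability models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The experiment

Gridded climate products get revised: a new release interpolates more
station data, shifts pixel values, and changes the correlation structure
among bioclimatic variables. Habitat suitability models (HSMs) fitted on the
old and the new release of the *same* product can therefore disagree, and
the size of that disagreement depends on the species' climatic niche, the
grid resolution, and the projection scenario. `hsmismatch` implements a
virtual-ecologist version of this question: because the species are
simulated with known climate–occurrence relationships, every prediction can
be compared against the truth that generated it, and the between-version
mismatch can be attributed to the factors under experimental control rather
than to unknowable field noise.

The pipeline is a fixed sequence, each stage an exported function:

1. **Synthetic climate** (`generate_climate_pair`): paired dataset versions
   A and B with resolution and future-scenario variants.
2. **Virtual species** (`simulate_suitability`, `occurrence_probability`,
   `realize_presence_absence`, `sample_presabs`): suitability from response
   curves or a PCA-space niche, logistic conversion to occurrence
   probability, Bernoulli presence–absence, and buffered virtual sampling
   with imperfect detection.
3. **Spatial blocking** (`full_data_residuals`, `build_correlogram`,
   `estimate_sac_range`, `choose_block_size`, `checkerboard_folds`):
   residual Moran's I correlograms set the checkerboard block size.
4. **Fitting and gating** (`fit_hsm`, `evaluate_hsm`, `select_models`,
   `ensemble_wmean`, `permutation_importance`): four learner families,
   AUC/TSS gates, AUC-weighted ensembles, standardized permutation
   importance.
5. **Projection and mismatch** (`project_models`, `median_projection`,
   `version_difference`, `predicted_simulated_r`, `hexbin_summary`).
6. **Factor importance** (`assemble_outcomes`, `rf_factor_importance`).

`run_experiment()` executes the whole factorial design; the numbered
scripts under `analysis/` run it stage by stage and write tables under
`results/`.

## The synthetic climate generator

Real studies of this kind download the two releases of a global climate
product. Here a generator replaces the download so the whole experiment is
self-contained and seeded. Each variable on the native grid (default 60 × 60
cells of 10 km, a 600 km planar extent) is

$$X_j = \mu_j + g_j\,\ell + \sigma_j F_j,$$

where $\ell$ is a linear north–south gradient, $F_j$ a unit-variance random
field obtained by convolving white noise with a Gaussian kernel (bandwidth =
`spatial_correlation_length`, default 80 km), and $(\mu_j, g_j, \sigma_j)$
per-variable location/gradient/anomaly scales. The defaults give two
temperature-like variables (annual mean `bio1` ~0–20 °C north to south,
diurnal range `bio2` ~9 °C), a wet-quarter temperature analogue (`bio3`), and
two precipitation-like variables (`bio4` ~80–140 mm, `bio5`), so the shipped
species presets can be phrased on meaningful scales.

Version B shares the deterministic part and mixes the anomaly with an
independent field,

$$F^B_j = \sqrt{1-d_j}\,F^A_j + \sqrt{d_j}\,F^I_j,$$

so the decorrelation parameter $d_j \in [0,1]$ maps monotonically from
bit-identical versions to independent anomalies while preserving the
marginal variance. The default vector decorrelates the diurnal-range
analogue most strongly ($d = 0.3$ vs 0.05–0.1 elsewhere), reproducing the
reported empirical pattern that variability-type variables agree least
between product versions while between-version pairwise r stays above
~0.85 for every variable. Future variants add a per-scenario shift (warming
for the temperature variables, drying for precipitation; the earlier
timeframe receives half the shift) plus a smoothed per-GCM perturbation
field expressed as a fraction of each variable's anomaly sd.

What the generator deliberately does *not* emulate: coastlines and nodata
geometry of a real continent (masks are supported but default to empty),
geographic coordinates and reprojection artefacts, cross-variable
correlation constraints beyond what the shared gradient induces, and any
change in cross-variable correlation under future scenarios. Passing tests
on this landscape therefore show that the *pipeline* behaves as specified,
not that any particular real-world mismatch magnitude is reproduced —
which is also why acceptance focuses on the factorial model count and on
direction-only properties rather than on the published mismatch values,
which depend on the real climate surfaces.

## Virtual species

Two niche constructions are supported. Response-curve species multiply
sigmoid / Gaussian-bell / threshold-logistic responses over named variables
and min–max rescale the product to [0, 1]. PCA-niche species fit a PCA on a
seeded background sample of standardized cell vectors (default 1000 cells)
and place a product-Gaussian niche at a chosen (PC1, PC2) center; broad
breadths give a climate-tolerant species, narrow off-center breadths a
sparse, restricted one. Density estimation in PC space is intentionally a
Gaussian product rather than a kernel density: the niche here *generates*
the truth, it does not describe data.

Suitability converts to occurrence probability with
$P = 1/(1+\exp((HS-\beta)/\alpha))$, which is exactly 0.5 at $HS = \beta$
and strictly increasing for $\alpha < 0$; the four shipped presets use the
conversion parameters α = −0.01, β = 0.4 (generalist), α = −0.05 with
β = 0.6 / 0.7 / 0.8 (alpine / mediterranean / restricted), and detection
probabilities 0.75 (0.9 for the restricted species). The response-curve
locations themselves are calibration choices on the synthetic variable
scales, set once so the archetypes land near their intended extent-wide
prevalences (~0.25 alpine, ~0.1 mediterranean, ~0.75 generalist, ~0.01–0.03
restricted) — the published curve parameters live in an unpublished
supplement and would be meaningless on synthetic scales anyway.

Sampling draws 50 samples of 300 cells (defaults). Climate-constrained
species use buffered sampling: disks around a seeded set of up to 500
presence cells (all of them, with a warning, if fewer exist) define the
eligible area, which raises sample prevalence above extent prevalence and
keeps discrimination estimates meaningful for sparse species. Buffers are
120 km for the alpine and mediterranean presets and 100 km for the
restricted one — tighter, preserving the design's ordering, but scaled up
from the original 60 km so a 300-point sample fits inside the buffered area
of a 600 km extent. Detection error applies at sampling time: a sampled
presence is recorded with probability *d*, absences are recorded
faithfully. Species–climate disequilibrium is out of scope by design.

## Spatial blocking

Full-data smoother (mgcv GAM) and boosted-trees fits provide residuals
(label − predicted suitability); Moran's I per 100 km distance class forms
the correlogram, and the SAC range is formalized as the center of the first
class with $I \le 0.05$ — a reproducible stand-in for the visual estimation
this rule replaces, falling back to the largest class edge with a warning
when no class crosses. The block size is the maximum SAC range over
algorithms plus 100 km. Blocks tile from the grid origin with no random
offset; folds alternate by block parity, and both the primary and the
complementary blocks-to-folds assignment are always evaluated, so each
sample contributes two train/test splits. Points on a shared block edge
belong to the lower-index block (half-open convention).

## Learners, gating, ensembles, importance

The four families use fixed, commonly used parameterizations — no
per-species tuning, since mismatch under *routine* protocols is the object
of study: binomial GLM with quadratic terms; mgcv GAM with GCV smoothness
selection and basis dimension capped by the training size (GAM is known to
calibrate poorly under this default; it is documented, not tuned); xgboost
with logistic loss, 100 rounds, depth 3, η = 0.1; and a 500-tree
classification forest whose suitability is the fraction of presence votes.
Predictions are clipped to [10⁻⁶, 1−10⁻⁶] so downstream correlations never
degenerate. Models pass the gate when test AUC ≥ 0.7 **and** TSS ≥ 0.4
(inclusive); an empty retained set is legal and recorded. Retained models
form an AUC-weighted ensemble ($w_i = \mathrm{AUC}_i/\sum \mathrm{AUC}$),
tagged `HSM_unique` when only one member survives. Permutation importance
is algorithm-independent: permute one variable's column, score
$1 - r(\hat p, \hat p_{perm})$, average over 5 permutations, clip negatives,
and rescale to percentages summing to 100.

## Mismatch diagnostics and factor importance

Per context (version × resolution × scenario × GCM × timeframe), the
per-sample ensemble projections reduce to a per-cell median (only samples
with at least one retained model contribute; the contributing count is
reported with every median grid). Between-version mismatch is the per-cell
difference B − A of median predictions; predicted-simulated r is Pearson's
correlation between the median prediction and the simulated occurrence
probability over seeded 10,000-pixel samples (capped with a warning on
smaller grids); hexagonal summaries of the (simulated, predicted) plane use
flat-top hexagons of width 0.04 anchored at the origin, so counts are
reproducible bit-exactly. Factor importance refits a 1000-tree regression
forest of each outcome on the one-hot-encoded experiment factors
(mtry = ⌊p/3⌋, minimum 1 — the regression-forest convention, chosen over a
cube-root reading) and permutes all dummy columns of a factor as a block so
levels stay coherent.

## Numerical choices and degenerate inputs

* Seeds: every stage derives a sub-seed from the master seed through a
  string-hash (`derive_seed`), so any single fit is reproducible in
  isolation and all seeds stay below 2³¹.
* Min–max rescaling of a constant suitability surface is an error naming
  the degenerate cause, as is a zero-variance vector in any correlation.
* TSS scans thresholds in steps of 0.01; ties resolve to the lowest
  threshold. AUC uses midranks, identical to pair counting with ties at 0.5.
* The logistic conversion saturates in double precision beyond ~40 logistic
  units; monotonicity is strict wherever the representation has headroom.
* Moran's I distance classes are half-open `(low, high]` with the first
  class closed at zero; classes with no pairs are masked.
* Stepwise VIF drops the worst variable while max VIF > 10; exact
  collinearity yields infinite VIF and is dropped first; a single surviving
  variable is assigned VIF 1.
* xgboost boosters are stored together with their serialized bytes; if the
  in-memory handle is invalidated (an external-pointer lifecycle hazard),
  prediction transparently reloads from the bytes.

## Problem sizes

The reference factorial design (2 versions × 3 resolutions × 50 samples ×
4 algorithms × 2 fold assignments = 2400 models per species) is what
`count_fits()` reports. The test suite and the acceptance script exercise a
smoke-scale instance chosen as the package's working example: a 60 × 60 grid,
two archetypes, 2 versions × 2 resolutions × 5 samples × 4 algorithms × 2
assignments (160 fitted models per species), with 10 × 1000-pixel
predicted-simulated samples; the direction-only properties (mismatch
monotonicity, fidelity to the generating version) run on 40 × 40 grids with
GLM-only reduced designs over 5 decorrelation levels × 10 seeds and 10
seeds respectively. These sizes are the package's own desk-scale choices;
all of them are plain arguments, and the full-scale design runs unchanged
by passing the reference configuration.

## Known limitations

Planar km geometry only (no CRS handling); the synthetic landscape cannot
validate absolute mismatch magnitudes, only the machinery and the
qualitative factor structure; the GAM default is deliberately left in its
poorly calibrated routine form; hexbin summaries and ASCII-grid outputs are
meant for inspection and plotting outside the package (no cartography); and
the pipeline is sequential — the factorial loop is embarrassingly parallel
but is kept single-process for determinism.
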