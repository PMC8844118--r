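# hsmismatch

When a gridded climate product is revised — more stations, new
interpolation, shifted pixel values — habitat suitability models (HSMs)
fitted on the old and new release of the *same* product can disagree, and
the disagreement depends on the species' climatic niche, the grid
resolution, and the projection scenario. `hsmismatch` implements a
virtual-ecologist experiment that quantifies this **between-version
mismatch** end to end, for ecologists and methodologists who want to probe
how much of an HSM prediction is signal and how much is climate-surface
provenance.

Because real product releases are external downloads, the package ships a
seeded synthetic-climate generator that emulates the statistical features
the analysis depends on: bioclim-style variables with latitudinal gradients
and spatially autocorrelated anomalies, a second version
`B = sqrt(1-d)·A + sqrt(d)·independent` per variable (decorrelation `d`
maps monotonically from identical to independent), coarser-resolution
aggregates, and future scenario × GCM × timeframe variants. Everything
downstream is the standard HSM protocol:

* virtual species with known climate–occurrence relationships
  (response-curve or PCA-space niches), logistic conversion
  `P = 1/(1 + exp((HS − β)/α))` to occurrence probability, Bernoulli
  presence–absence, buffered sampling with imperfect detection;
* residual Moran's I correlograms → spatial-autocorrelation range → 
  checkerboard spatial-block cross-validation (block size = SAC range +
  100 km, both fold assignments);
* four learners (GLM, GAM, boosted trees, random forest), gated at test
  AUC ≥ 0.7 and TSS ≥ 0.4, combined into AUC-weighted ensembles with
  standardized permutation importance (percentages summing to 100);
* projections per context, per-cell median surfaces, between-version
  difference grids, predicted-simulated Pearson r, hexagonal summaries;
* random-forest factor-importance analysis (1000 trees, block permutation
  of one-hot factors) of the experimental factors.

The reference factorial design — 2 versions × 3 resolutions × 50 samples ×
4 algorithms × 2 fold assignments — fits **2400 models per species**
(`count_fits()`).

## Worked example

A desk-scale run (60 × 60 km grid, two archetypes, 2 versions × 2
resolutions × 5 samples × 4 algorithms × 2 assignments = 160 models per
species):

```r
library(hsmismatch)
cfg <- smoke_config(master_seed = 1)
res <- run_experiment(cfg, out_dir = "results/experiment", verbose = TRUE)
```

prints, among other progress lines:

```
alpine A res1: 5/5 samples with retained models
...
mediterranean B res2: 5/5 samples with retained models
```

and the stage-4 analysis script summarizes the result tables:

```
fitted 320 models (160 per species); 82% passed the AUC >= 0.7 & TSS >= 0.4 gate
  gam  median test AUC 0.815, RMSE 0.396
  gbm  median test AUC 0.813, RMSE 0.318
  glm  median test AUC 0.799, RMSE 0.401
  rf   median test AUC 0.836, RMSE 0.330
current-climate between-version mismatch (median |B - A| of median HS):
  alpine         res1  0.0106
  mediterranean  res1  0.0103
median predicted-simulated r by species x version:
  alpine         A 0.973
  alpine         B 0.966
  mediterranean  A 0.839
  mediterranean  B 0.733
```

Read: all 320 models of the factorial smoke design were fitted; the gate
passed 82% of them; the two dataset versions disagree by ~0.01 suitability
units at the median pixel under current climate; and models fitted on the
generating version (A) track the simulated occurrence probability more
closely than models fitted on the perturbed version (B) — the core
mismatch signal, strongest for the archetype whose driver variables
decorrelate most.

The numbered scripts under `analysis/` run the pipeline stage by stage
(climate + VIF selection, virtual species, blocking, fitting/projection,
factor importance), each writing CSV/ASCII-grid tables under `results/`.

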