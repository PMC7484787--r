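# tpeflim

Label-free identification of resting vs. activated dermal mast cells
from two-photon excited fluorescence lifetime imaging (TPE-FLIM),
rebuilt as a tested R pipeline on ground-truthed synthetic data.

Mast cells drive urticaria, mastocytosis and other skin diseases, and
assessing their number and activation state normally requires a biopsy.
In TPE-FLIM, every pixel carries a TCSPC photon-arrival histogram; a
bi-exponential decay model

    m(t) = IRF * ( a1·exp(-t/τ1) + a2·exp(-t/τ2) ),
    τ_m  = (a1·τ1 + a2·τ2) / (a1 + a2)

separates resting mast cells (τ_m > 1,000 ps, dim) from
activated/degranulated ones (τ_m < 800 ps, bright), from the
elastin-dominated matrix (τ_m ≈ 1,600 ps) and from near-zero-lifetime
capillaries. The package provides:

* `generate_cohort()` / `render_scene()` — a synthetic-data generator:
  feature-level 407-cell cohorts drawn from the per-class
  lifetime/amplitude/intensity tables, and full TCSPC decay cubes
  (elastin background, capillaries, granule-textured cells, IRF
  convolution, Poisson noise) with ground truth.
* `bin_decays()`, `fit_pixel()`, `fit_image()` — spatial binning
  (b = 3: 48 neighbors + center) and per-pixel IRF-convolved
  bi-exponential weighted least squares (model-weighted IRLS,
  equivalent to the Poisson MLE), with 200/800 photons/mW intensity
  masking.
* `phasor_transform()`, `phasor_image()` — first-harmonic phasor
  coordinates with IRF calibration and the 70% intensity threshold.
* `detect_bright_spots()`, `measure_cell()`, `mc_search()` — the
  in vivo mast-cell search cascade (depth > 70 µm, ≈10 µm size window,
  fibroblast exclusion > 20 µm, τ_m gates).
* `build_features()`, `grow_tree()`, `evaluate()` — the
  265-dimensional feature vector (1 shape + 1 intensity + 256 decay
  channels + 7 decay parameters), a from-scratch Gini CART (depth 6,
  min split 2) with a compiled split search, and the 1,000-repeat
  randomized 60/40 sensitivity/specificity protocol.
* `ks_two_sample()`, `population_compare()`, `segmentation_scatter()` —
  the descriptive statistics used throughout.
* `run_pipeline()` plus numbered drivers under `analysis/` tying the
  stages together; TIFF + JSON decay cubes and CSV tables as the
  on-disk formats.

## Worked example

```r
library(tpeflim)

cohort <- generate_cohort(seed = 11)   # the 407-cell synthetic cohort
nrow(cohort)                           # 407, of which 250 are mast cells
evaluate(cohort, "binary", n_repeats = 100, base_seed = 11)
```

```
Decision-tree evaluation (binary, 100 repeats, 40% test)
  class 0: sensitivity 0.92 +/- 0.03, specificity 0.86 +/- 0.05
  class 1: sensitivity 0.86 +/- 0.05, specificity 0.92 +/- 0.03
```

Class 0 is "mast cell": across 100 randomized 60/40 train/test splits,
the tree recovers 92% of mast cells and rejects 86% of other dermal
cells — close to the published operating point, with the gap set by the
overlap of the class distributions (macrophage, dendritic and
neutrophil lifetimes overlap the mast-cell bands; that overlap is the
reason a classifier is needed at all).

Fitting a cell-free rendered scene recovers the elastin background:

```r
scn <- render_scene(scene_config(image_size = 24), seed = 5)
fm  <- fit_image(scn$cube)             # binning 3, 200 photons/mW mask
mean(fm$maps$tau_m[fm$valid])          # 1595.6 ps  (generator: 1600 ps)
```

The `analysis/` scripts run the full narrative in order
(`01_simulate.R` … `06_stats.R`), writing cohort, decay cube, fit maps,
phasor clouds, detected-cell tables, classifier reports and population
statistics under `results/`.

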