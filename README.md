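# weedspec

Identification of arable weed species from VNIR (400–1000 nm) hyperspectral
reflectance images, built as a tested R package plus a numbered analysis
workflow. The target users are plant scientists and agronomy/remote-sensing
groups who want a reproducible, end-to-end reference pipeline for
hyperspectral species discrimination — from raw hypercubes to classifier
comparison — without access to a proprietary imaging workstation.

The package covers nine weed species common in spring-wheat fields
(*Convolvulus arvensis*, *Erigeron canadensis*, *Erysimum cheiranthoides*,
*Sonchus arvensis*, *Capsella bursa-pastoris*, *Artemisia vulgaris*,
*Ambrosia artemisiifolia*, *Amaranthus retroflexus*, *Chenopodium album*).
Because the original image archive is not public, a first-class synthetic
generator reproduces the study design: 25 plants per species, 2–3 regions of
interest (ROIs) per plant with ≥ 50 pure pixels each, 601 ROIs overall with
the reported per-species imbalance, species-specific visible (5–14 %) and
near-infrared (16–26 %) reflectance levels, part-dependent signatures
(leaves/stems with a red-edge rise; roots, basal zones and white flowers with
a bright 550–750 nm plateau), plant-level biological variability and
pixel-level sensor noise.

## What it computes

* **Hypercube I/O and calibration** — ENVI header + binary cubes (BIL/BSQ/BIP),
  dark/white reference calibration `R = 100·(raw − dark)/(white − dark)`,
  pseudo-RGB and max-variance projections.
* **Preprocessing** — moving-average smoothing (shrunk-edge rule), then the
  standard normal variate transform `SNV(x) = (x − x̄)/σₓ` (population σ),
  in that fixed order; no band trimming.
* **Pixel PCA** — mean-centred, unscaled PCA with variance accounting
  against the full covariance trace: explained variance
  `λᵢ / Σλⱼ · 100 %` and its cumulative form, plus density-coded
  (t1, t2) score scatters.
* **Spectral-signature statistics** (500–780 nm window) — per-part
  reflectance ranges aggregated to species level by unweighted part means:
  mean reflectance μ, delta reflectance ΔR = R_max − R_min, spectral
  bandwidth SB = λ_max − λ_min, contrast ratio C = λ_max/λ_min, relative
  bandwidth B_rel = (λ_max − λ_min)/(λ_max + λ_min), normalised contrast
  C_norm = (λ_max − λ_min)/λ_max.
* **Classification** — plant-wise grouped 70/30 split (ROIs of one plant
  never straddle train/test), five classifiers at fixed hyperparameters:
  random forest (100 trees, 11 features per split), linear SVM (C = 1,
  one-vs-rest), single-hidden-layer logistic neural network (width
  auto-selected), maximum-entropy multinomial logistic regression
  (λ = 0.001), and a from-scratch SIMCA (per-class PC1–PC2 models,
  assignment by smallest orthogonal distance); plant-grouped stratified
  5-fold cross-validation with grid search.
* **Evaluation** — confusion matrices, per-class precision/recall/F1,
  macro/micro accuracy, log loss (nats) and log-loss reduction against the
  class-prior baseline, and deterministic classifier ranking.

## Worked example

```r
library(weedspec)

# species-level statistics recomputed from the published part ranges
st <- stats_table(reported_part_ranges())
st[1, c("species", "mu", "delta_r", "sb", "c", "b_rel", "c_norm")]
#>                species       mu  delta_r       sb        c   b_rel c_norm
#> 1 Convolvulus arvensis 22.58333 16.83333 246.6667 1.465455 0.18821 0.3162

# simulate the study cohort and run the classifier comparison
co    <- generate_cohort(roi_counts = weed_roi_counts(), seed = 1)
feats <- roi_features(co)                       # SNV-smoothed mean spectra
plan  <- plant_wise_split(co, 0.7, seed = 2)
tr    <- setNames(plan$role, plan$plant_id)[feats$plant] == "train"
rf    <- train_classifier(feats$x[tr, ], "rf", y = feats$y[tr], seed = 3)
rep   <- evaluation_report(feats$y[!tr],
                           predict(rf, feats$x[!tr, ], type = "prob"),
                           priors = rf$priors, algorithm = "rf")
rep
#> <evaluation_report> rf, 189 samples
#>   accuracy 95.2%  macro 0.96  micro 0.95  log loss 0.162  log-loss reduction 0.924
```

Here `mu` is the species' mean reflectance (%) over its morphological parts,
`delta_r` the mean within-part reflectance range, `sb`/`c`/`b_rel`/`c_norm`
the wavelength-domain bandwidth and contrast measures; the evaluation line
reports held-out plant-wise test accuracy, class-averaged (macro) and
sample-averaged (micro) accuracy, probabilistic log loss and its reduction
over the class-prior baseline.

The full workflow is scripted under `analysis/` (run in order):

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + design tables
Rscript analysis/02_pixel_pca.R         # variance accounting, score scatter
Rscript analysis/03_spectral_metrics.R  # published + measured metric tables
Rscript analysis/04_classification.R    # five classifiers, reports, ranking
```

Each stage prints what it found and writes its tables under `results/`.

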