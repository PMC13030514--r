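---
title: "Methods: simulating and classifying weed hyperspectral signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying weed hyperspectral signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedspec)
```

## The problem

Weed species growing in the same field share growth conditions and hence
broadly similar reflectance curves: strong pigment absorption in the visible
range (VIS, here taken as 500–700 nm), a sharp "red-edge" rise between
roughly 690 and 740 nm, and a bright near-infrared plateau (NIR, 700–780 nm
in the operational window). Species identity is encoded in second-order
features — the VIS and NIR reflectance *levels*, the red-edge *position and
steepness*, the green-peak *amplitude* near 550 nm — and in how these differ
between morphological parts of the plant. weedspec implements a complete
analysis chain for this discrimination problem: hypercube calibration and
I/O, spectral preprocessing, pixel-level PCA, ROI handling with plant-wise
validation splits, a battery of descriptive spectral statistics, five
classifiers, and a common evaluation surface.

Because the underlying image archive is not public, the package ships a
synthetic-data module that is itself first-class, tested code. Every
downstream stage is exercised against cohorts whose *statistical* structure
matches the study design; no binary data are shipped.

## The spectral model

A species profile holds five anchor parameters: the VIS window mean
reflectance $V$, the NIR window mean $N$ (both in %, $N > V$ for
vegetation), the red-edge centre $c \in [690, 740]$ nm, the red-edge
logistic width $w$, and the 550 nm green-peak amplitude $A$. A
chlorophyll-bearing part (leaf, stem) is rendered as

$$r(\lambda) = a + b\,\sigma\!\left(\frac{\lambda - c}{w}\right)
  + A e^{-(\lambda - 550)^2 / (2 \cdot 25^2)},$$

with $\sigma$ the logistic function. The baseline $a$ and rise amplitude
$b$ are *solved* (on an internal 1 nm grid) so that the 500–700 nm and
700–780 nm window means equal $V$ and $N$ exactly. This calibration makes
the anchors directly recoverable from window means of rendered spectra — the
basis of the parameter-recovery test — at the cost that the spectrum *at*
780 nm sits slightly above $N$ (a window mean is below the plateau it ends
in). Root, basal and white-flower parts replace the rise with a bright
plateau between a rise near 565 nm and a drop near 750 nm (both shifted with
the species' red-edge centre, so below-ground signatures remain
species-specific); their VIS level is at least their NIR level by
construction. Yellow flowers use a gentle elevated ramp.

Default anchors for the nine species place $V$ between 5 % (*Convolvulus
arvensis*) and 14 % (*Capsella bursa-pastoris*, *Chenopodium album*) and $N$
between 16 % (*Erysimum cheiranthoides*) and 26 % (*Amaranthus
retroflexus*), the reported whole-plant window levels. Red-edge centres
(700–726 nm), widths (7–14 nm) and green-peak amplitudes (1.2–3.0 %) are
package choices within the physiologically ordinary range, spaced so that
species differ in curve *shape* as well as level — which is what the
imbalanced-cohort classification regime (below) requires.

## Noise model and what it emulates

Variability is layered in two tiers, mirroring how laboratory imaging
variability actually decomposes:

* **pixel level** — a multiplicative gain per pixel (sd 0.05) and additive
  per-band noise (sd 0.5 % reflectance): illumination texture and sensor
  noise;
* **plant level**, drawn once per plant and shared by all its ROIs — a
  multiplicative gain (sd 0.06), an additive offset (sd 1 %), a red-edge
  centre shift (sd 1.5 nm) and a VIS–NIR contrast factor (sd 0.04):
  biological variability in pigment content and canopy structure.

The two shape terms (red-edge shift, contrast factor) matter because SNV
removes additive offsets and multiplicative gains *exactly*; without
shape-level variability every ROI of a species/part pair would collapse to
one noise-free spectrum after preprocessing and all classifiers would be
trivially perfect. Their magnitudes were calibrated once against the
reported class-separability regime (random-forest plant-wise test accuracy
in the low-to-mid 90s on the imbalanced 601-ROI cohort) and then frozen;
they correspond to red-edge position scatter of a few nanometres, the
ordinary chlorophyll-driven range. With all six standard deviations set to
zero the generator is exactly deterministic, which the tests exploit.

A single global seed derives one seed per plant, so any plant is
regenerable in isolation and cohorts are bit-reproducible.

## Design choices that were genuinely open

* **Window means as anchors.** The species levels are defined as VIS/NIR
  *window means* of the rendered curve rather than peak values; this gives
  an exact, testable calibration target.
* **Parameter recovery is assessed on leaf ROIs** (the parts without
  offsets) and "within 2 sampling sds" is read as two standard deviations of
  the per-plant species means. This tests calibration *bias* — the
  scientifically meaningful failure mode — rather than staking a
  deterministic test on a ~95 % coverage event.
* **Part mix.** The paper-level sources do not state per-part ROI counts;
  the generator cycles leaf → stem → root per plant (configurable), keeping
  above-ground tissue dominant.
* **Aggregation rule for the species statistics.** The species-level tables
  are unweighted arithmetic means over all listed parts (including the
  whole-plant "General" row): the part *midpoint* for μ, the part *range*
  for ΔR, and per-part wavelength statistics for SB, C, B_rel and C_norm.
  This is the only simple rule that reproduces the published species rows
  from their own part ranges, and duplicating parts leaves it unchanged. One
  published value (*Amaranthus retroflexus* SB = 238.0 nm) is inconsistent
  with its own part ranges under any unweighted mean (250 nm) and is treated
  as a typographic error; the secondary descriptors σ, CV, Me and the rate
  of change R are computed from the same part set but flagged
  `non_reconciled`, since values printed from raw spectra cannot be
  recovered from range data.
* **Split rounding.** The plant-wise split takes
  `floor(train_fraction · n_plants)` training plants per species (25 plants
  at 0.7 → 17/8); no rounding rule was stated.
* **"Maximum entropy" classifier.** Implemented as L2-regularised
  multinomial logistic regression (decay λ = 0.001); the named solver in
  the original toolchain is an optimisation detail, not a model.
* **Neural network width.** "Auto-selected" is realised as
  $\lceil\sqrt{p\,K}\rceil$ hidden units (geometric mean of input and
  output dimension); iteration budget is the fitting library's default
  (100). A documented default beats silence.
* **SVM probabilities.** One-vs-rest linear SVMs with a softmax over
  oriented decision values — an explicit approximation, needed only for log
  loss.
* **SIMCA.** Per-class mean + PC1–PC2 loadings; orthogonal distance is the
  residual norm after projection onto the class plane; assignment is the
  argmin with ties to the smaller class index; each class records the 95th
  percentile of its training distances as a critical threshold. This is the
  one algorithm written from scratch, and it is verified against a
  brute-force projection oracle to 1e-10.
* **Reflectance clipping.** Calibrated reflectance is clipped to
  [0, 120] % — real calibrations overshoot slightly and the 120 cap
  preserves specular flags for the ROI-level specular filter. Bands where
  white equals dark are set to missing and flagged. Whether the original
  toolchain clips super-unity reflectance is unknown; this is an artifact
  decision.
* **PCA conventions.** Mean-centred, unscaled covariance PCA (reflectance
  units are homogeneous across bands); explained percentages are taken
  against the trace over *all* bands so they remain well-defined with k = 6
  retained components; loading signs are fixed by making each column's
  largest-magnitude element positive.

## Numerical details

Moving-average smoothing uses a truncated (shrunk) window at the spectrum
edges, so output length equals input length and constants are preserved;
the operator is linear. SNV uses the population (divisor-n) standard
deviation and rejects zero-spread spectra. Log loss is natural-log with
probabilities clipped to [1e-15, 1]; log-loss reduction is
$1 - \mathrm{LL}_{\mathrm{model}} / \mathrm{LL}_{\mathrm{prior}}$ against
the training class-frequency predictor. Undefined precision (a class never
predicted) is reported as 0 with an explicit flag so macro averages stay
well-defined. Classifier ranking orders by accuracy, then ascending log
loss, then algorithm id — deterministic under permutation of its input.

Problem sizes used throughout the tests and the acceptance script are the
package defaults: a 61-band grid (the full 1200-channel, 0.5 nm grid is
configurable), 60 pixels per ROI, 601 ROIs. At these sizes the full
pipeline — simulation through five trained classifiers — completes in well
under a minute on one CPU.

## What passing tests do and do not show

The generator reproduces the *statistical* structure the study reports:
anchor levels, part-dependent curve families, cohort design, ROI imbalance,
plant-grouped validation difficulty, and a classification regime in which
the random forest reaches ≥ 90 % plant-wise test accuracy and beats the
single-hidden-layer network. It does not reproduce pixel-wise appearance of
real plants, spatial texture, specular geometry, water-band features, or
SWIR (> 1000 nm) behaviour. Two honest divergences from the real-data
results deserve note. First, the synthetic classes are closer to
Gaussian-with-shared-structure than real tissue spectra, so the *linear*
models (SVM, maximum entropy) and SIMCA perform far better here than their
reported real-data accuracies (60.1 %, 63.7 %, 51.7 %) — on some draws the
maximum-entropy model ties or edges the forest. Second, per-class
confusion patterns depend on the random plant draw and are not comparable
class-by-class with the published confusion matrices. Conclusions that
transfer are therefore about *pipeline correctness and protocol* (leak-free
splitting, variance accounting, metric identities, reproducibility), not
about real-world algorithm rankings.
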