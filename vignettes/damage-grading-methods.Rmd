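---
title: "Grading defoliation damage from UAV canopy imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading defoliation damage from UAV canopy imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needlegrade)
```

## The problem

Leaf-feeding pests such as the larch-defoliating geometrid *Erannis
jacobsoni* strip conifer needles progressively, and the canopy of an
affected tree shifts in colour from green through yellow and red to grey
as damage advances. Ground surveys grade each tree by its **leaf-loss
rate**

$$DR = \frac{L_d}{L_h + L_d} \times 100\%$$

where $L_h$ and $L_d$ are counted healthy and damaged needles, and bin
the rate into four levels: Healthy ($DR \le 5$), Mild ($5 < DR \le 30$),
Moderate ($30 < DR \le 70$) and Severe ($DR > 70$). Field grading is
accurate but slow; this package implements the image-analysis pipeline
that replaces it with per-tree features from UAV orthomosaics:

1. **Vegetation indices.** Per-pixel algebraic combinations of camera
   channels (`RGB_VI`, e.g. ExG $= 2G - R - B$, CIVE, R/G ratios) or of
   five-band multispectral reflectances (`MS_VI`, e.g. NDVIreg
   $=(NIR - RE)/(NIR + RE)$), averaged over each digitised canopy.
2. **Texture.** The first principal component of the RGB channels is
   quantised and a sliding-window grey-level co-occurrence matrix (GLCM)
   yields eight Haralick-style statistics (mean, var, hom, con, dis,
   ent, sm, corr), again averaged per canopy (`RGB_TF`).
3. **Screening and selection.** One-way ANOVA F of each feature against
   the damage level flags sensitive features; the successive projections
   algorithm (SPA) then extracts a small low-collinearity subset.
4. **Classification and evaluation.** A random forest and a small 1-D
   convolutional network predict the four levels from the selected
   features; performance is reported as overall accuracy (OA), Cohen's
   kappa, and per-class user/producer accuracy from the confusion
   matrix, across a sample-size sweep.

The half-open level bands deserve a note: the field convention prints
integer bands (0–5, 6–30, 31–70, 71–100), which leaves fractional rates
such as 5.4 unmapped. `classify_level()` uses inclusive upper edges at
5, 30 and 70, which preserves every printed integer's membership while
covering the continuum.

## The synthetic scene generator

Real orthomosaics of graded trees are rarely shareable, so the package
carries a generator whose output has the statistical structure the
analysis assumes, making every downstream stage testable end to end.
`generate_scene()` renders each tree as a filled ellipse with jittered
radii on a non-overlapping grid (masks are disjoint by construction and
at least 9 pixels), on a speckled background.

The defaults are the package's fixed study conditions:

* **Layout** — 210 trees in each of the four classes (840 total), a
  420 px square raster, canopy semi-axes of 4–6 px.
* **Colour** — class mean (R, G, B) reflectances (0.20, 0.45, 0.18),
  (0.45, 0.48, 0.20), (0.55, 0.35, 0.18), (0.40, 0.40, 0.40): the
  green → yellow → red → grey progression. Each tree's base colour is
  jittered around its class mean with `class_color_sd = 0.07` per
  channel. This within-class spread was calibrated so neighbouring
  classes overlap realistically (colour-only classifiers reach roughly
  0.9 overall accuracy, not 1.0) — within-class spectral variance is
  never published for such surveys, so the spread is set by the
  qualitative structure it must produce.
* **Texture** — per-pixel Gaussian noise with class-dependent standard
  deviation `texture_grain = (0.02, 0.04, 0.06, 0.09)`: progressive
  defoliation exposes branches and gaps, raising fine-scale contrast.
  Each tree multiplies its class grain by a lognormal factor
  (`texture_grain_jitter = 0.35` on the log scale). This per-tree
  variability matters: crowns differ widely in fine-scale texture, so
  texture separates classes much more weakly than colour. The jitter is
  calibrated jointly with the colour spread so that texture is an
  auxiliary signal — too weak to classify well alone, yet complementary
  enough that adding it to the colour features helps — rather than a
  second, independent label or pure noise.
* **Shadow** — 15% of each canopy's pixels are darkened by a factor of
  0.5, emulating the intra-crown shadow that is the dominant feature
  noise in real orthomosaics.
* **Multispectral planes** (optional) — five bands (b, g, r, RE, NIR)
  with class-mean NIR declining from 0.45 (healthy) to 0.22 (severe),
  since defoliated crowns lose the leaf-internal scattering that drives
  NIR reflectance; the red edge declines more gently.

Ground truth is drawn first: needle counts per tree are chosen so that
$DR$ lands strictly inside the class band, with a 0.5 % safety margin so
integer rounding cannot cross a boundary — re-deriving the level from
the counts therefore recovers the generating class for every tree.

What the generator does **not** emulate: radiative transfer,
orthorectification artefacts, crown overlap and understory mixing,
label noise from invisible lower-canopy damage, or between-site
illumination differences. Passing tests on synthetic scenes demonstrate
that the pipeline's statistics, selection and classification machinery
are correct and well composed — not that the same accuracy would be
reached on real forests.

## Numerical and algorithmic choices

* **Ratio indices.** Denominators that are exactly zero are padded with
  $\varepsilon = 10^{-9}$; reflectances are noisy non-negative floats
  and a hard per-pixel failure would be unusable. Indices named in the
  catalogue without a printed formula (VARI, GRVI, NGRVI, PPR, WI,
  ExGR, RGBVI) use their standard literature definitions and are
  flagged `literature` in `index_registry()`.
* **Normalisation.** Features are min–max scaled to [0, 1]; the bounds
  are stored on the table so held-out data can be scaled identically.
  Min–max (rather than z-scoring) keeps all features on the bounded
  scale the CNN input expects; constant features map to 0.
* **GLCM.** 32 grey levels by linear binning of the PCA component's
  global [0, 1] range (mask-independent, hence reproducible), 7×7
  window, the four standard unit offsets averaged, symmetric counts,
  reflective edge padding. These are common desk-scale co-occurrence
  settings in remote sensing. `texture_stats()` implements the standard
  Haralick forms; the variant forms that carry a leading $i$ factor
  inside the dis/ent/sm sums are kept behind `paper_literal = TRUE` for
  comparison, as some published tables print them that way. The
  correlation statistic is defined as 1 for a single-level (degenerate)
  window.
* **ANOVA conventions.** `anova_f()` uses the classical $k-1$ and
  $n-k$ degrees of freedom. The screening thresholds, however, follow
  the remote-sensing convention of quoting $F_{crit}$ at $(k, n)$ —
  `f_critical(0.01, 4, 840)` = 3.34 and `f_critical(1e-10, 4, 840)` =
  13.57 — and the sensitivity flags use those values. Perfectly
  separated features return an `Inf` sentinel and are flagged
  sensitive. The `1e-10` tail is the reading of the "extremely
  significant" threshold that reproduces 13.57.
* **SPA.** Classical chemometrics form: from every start feature, grow
  a chain by projecting all unselected columns onto the orthogonal
  complement of the selected span and appending the largest residual;
  chains stop at rank deficiency. Candidate prefixes of size
  $k_{min}..k_{max}$ are scored by validation misclassification of a
  nearest-class-centroid classifier on standardised features — cheap,
  deterministic, and model-agnostic relative to the downstream RF/CNN —
  with ties broken towards smaller subsets, then lexicographic feature
  order. SPA runs on the ANOVA-sensitive features only, matching the
  screening-then-selection narrative order.
* **Splits.** `make_split()` stratifies by class with a deterministic
  largest-remainder allocation (840 trees → exactly 630/210). Real
  surveys often split unstratified; `stratified = FALSE` reproduces
  that, but stratification is the default because small test sets
  otherwise lose whole classes.
* **Random forest** uses the `randomForest` package: 500 trees,
  $\sqrt{m}$ features per split, Gini importances normalised to sum 1.
* **CNN.** No small-network library exists in the R dependency set this
  package targets, so the 1-D network is implemented directly in matrix
  code: convolution (16 kernels, width 3, clipped to the feature count)
  → ReLU → max-pool (2) → dense (32) → softmax over the four levels,
  trained with mini-batch Adam (learning rate $10^{-3}$, batch 32, 200
  epochs) on cross-entropy. Feature order for the convolution is the
  SPA selection order — deterministic and selection-meaningful. Weight
  initialisation and batch shuffling are seeded, so a fixed seed gives
  identical predictions. Importances are the mean absolute input
  gradient of the training loss, normalised to sum 1. These
  hyperparameters were chosen for stability at the ≤ 840-tree scale and
  are recorded in `model_spec()`.
* **Sweep.** Sizes 140–840 in steps of 100; each cell draws an
  independent stratified subsample per seed (nested subsets would
  correlate adjacent sizes), splits 75/25, trains and evaluates. SPA
  selection is performed once per feature set on the full table; the
  sweep varies the training data, not the feature subset.
* **Evaluation.** Confusion matrices are oriented rows = predicted, so
  user accuracy is row-wise and producer accuracy column-wise. OA is
  trace/S — the multiclass reading of the two-class
  $(TP+TN)/(TP+TN+FP+FN)$ form, to which it reduces at $k = 2$ (a test
  asserts the equivalence). Kappa's degenerate case ($p_e = 1$) returns
  a flagged `NA` rather than an error.
* **Seeding.** `run_experiment()` derives named substreams (scene,
  split, spa, rf, cnn, sweep) from one root seed, all below $2^{31}$,
  and records them in the run manifest, so any run can be replayed.

## Problem sizes used in the test-suite

The suite exercises the full default scene (840 trees) where the claim
under test is about the default conditions — classifier accuracy, the
feature-set ordering over ten seeds, sweep structure — and small scenes
(tens of trees, ~100 px rasters) for algebraic and structural
properties, where scene size is irrelevant. Texture-ordering properties
are measured on canopy interiors (masks eroded by the window
half-width): boundary windows straddle canopy and background, so their
contrast reflects the colour-background gap, not the class's grain.

## Known limitations

* The generator's class structure is stylised; no claim is made that
  accuracy on synthetic scenes transfers to real forests (on real data
  the published pattern is mid-80s OA for RGB feature combinations).
* The full literature catalogues of 60 multispectral and 22 RGB indices
  are not reproduced; the registry carries the printed formulas plus
  the common literature definitions.
* GLCM parameters (levels, window, offsets) follow common practice but
  published studies rarely state theirs; results can shift with the
  window size relative to crown diameter.
* The CNN is intentionally small and CPU-bound; it is not a
  general-purpose deep-learning component.
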