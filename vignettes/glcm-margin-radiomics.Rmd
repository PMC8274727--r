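---
title: "Core and margin GLCM radiomics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core and margin GLCM radiomics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glcmrad)
```

## The problem and the model

Tumors that respond poorly to neoadjuvant chemotherapy tend to be
structurally more disorganized than responders, and that disorganization is
visible as image texture in T2-weighted MRI. The pipeline implemented here
quantifies texture with grey-level co-occurrence matrices (GLCMs) computed
separately from the tumor core and from peritumoral margin bands, and asks
whether simple classifiers on a handful of those features can separate
responders (R) from non-responders (NR) under leave-one-out
cross-validation (LOOCV). Non-responders — the rare class, and the one a
clinician most needs to find — are the positive class throughout, so
sensitivity means sensitivity to non-response.

The analysis chain is: per-slice binary masks (tumor core, breast tissue)
aligned to a grayscale slice stack → ROI selection → grey-level
quantization inside the ROI → masked, direction-averaged, slice-pooled GLCM
→ 11 scalar features → classifier with exhaustive small-subset feature
selection under LOOCV.

### ROIs

The margin band of width $w$ is the core dilated by a Euclidean disc of
radius $w$ (a pixel belongs to the dilation iff its center lies within $w$
of a core-pixel center), minus the core, intersected with breast tissue.
Dilation is strictly 2D per slice: ROIs are drawn per slice and slice
thickness generally differs from in-plane pixel size, so a voxel-unit 3D
dilation would be anisotropic. The band is an outer ring — it excludes the
core — so core and margin features are computed from disjoint tissue. An
inclusive variant (expanded region containing the core) would be a
one-line change, but the ring is the default because it isolates the
peritumoral signal. Bands of increasing width are nested
(band(5) ⊆ band(15)), and a band clipped by the breast boundary stays
exactly inside breast tissue.

### Quantization

Binning happens after ROI selection so tissue outside the ROI never
influences the grey-level range. The range is the in-ROI min–max pooled
over all of a patient's slices (not per slice), keeping a grey level's
meaning constant within a patient–ROI pair; labels are
$\lfloor N_g (x - \mathrm{lo}) / (\mathrm{hi} - \mathrm{lo}) \rfloor$
clamped to $N_g - 1$, and a constant ROI maps entirely to level 0.
$N_g \in \{16, 32, 64, 128, 256\}$.

### GLCM and features

Co-occurrence counts are accumulated over the four standard 2D offsets
$(0,d), (d,0), (d,d), (d,-d)$, with transposed counts added (symmetry),
pooled across slices, and normalized once at the end. Pooling raw counts
across directions before normalizing is the standard way to obtain
directionally invariant features; pooling across slices weights each slice
by its pair count rather than averaging per-slice features (a small slice
with few pairs should not count as much as a large one). A per-slice
averaging variant was considered and rejected as the default for that
reason. Offset distances $d \in \{1,2,3,4,5,10,15\}$ apply to the core;
margin bands are thin, so they are analyzed at $d = 1$ only — larger
offsets leave too few in-band pixel pairs, and the pipeline rejects any
other margin distance at validation.

GLCM indices are the 0-based quantized labels, which fixes the values of
the mean and variance features. Entropy uses the natural logarithm. The
correlation feature is undefined when the grey-level variance is zero
(constant ROI); it is reported as `NA` with a warning — never silently 0 —
and rows with missing values in the selected features are rejected by the
classifiers rather than imputed.

### Classifiers and evaluation

All four families see z-scored features, with means and standard
deviations estimated from the training fold only and applied unchanged to
the held-out row — GLCM features span orders of magnitude across
quantizations, and kNN and SVMs are scale-sensitive. A zero-variance
training feature keeps scale 1 (centering only) with a warning.

* **FLD**: $w \propto (S_W + \varepsilon I)^{-1}(\mu_{NR} - \mu_R)$ with
  $\varepsilon = 10^{-6}\,\mathrm{tr}(S_W)/p$; balanced 19-vs-19 fits with
  up to 4 features can be near-singular, and the small ridge makes them
  reproducible. The threshold is the midpoint of the projected class means.
* **SVM** (linear / RBF) via libsvm, grids $C = 2^1..2^{10}$,
  $\gamma = 2^{-15}..2^5$; the decision score is oriented so the NR side is
  positive.
* **kNN**: Euclidean distance, $k \in 1..5$; the score is the NR fraction
  among the $k$ neighbors. A vote tie predicts NR — deterministic, and it
  favors sensitivity on the rare class, which matters because even $k$ are
  in the grid. Distance ties break toward the lower row index.

Every model exposes a centered decision score (NR-positive, threshold 0),
which is what balanced-subsample aggregation averages: with balancing on,
each training fold is subsampled into `n_subsets = 25` balanced subsets
(all minority rows plus an equal-size majority draw without replacement),
one model is fit per subset with its own standardization, and the held-out
row's label comes from the mean score. Averaging scores rather than votes
yields a single ROC per configuration; 25 subsets keeps the majority-class
sampling error of the mean score small at this cohort scale.

Feature selection enumerates all $\sum_{k=1}^{4}\binom{11}{k} = 561$
subsets crossed with the hyperparameter grid and maximizes LOOCV accuracy
(or F1). Ties break toward the smaller subset, then the earlier subset in
canonical feature order, then smaller hyperparameters — deterministic and
biased toward parsimony. Selection runs once on the full table, outside
the LOOCV loop; this mirrors reporting a single feature list per
classifier, but the resulting LOOCV estimate is optimistically biased
because the held-out patient influenced which subset won. The unbiased
alternative (re-selecting inside every fold) multiplies cost by the fold
count and reports fold-dependent feature lists; the package keeps the
unnested estimate as the headline and documents the bias rather than
hiding the choice.

AUC comes from the pooled LOOCV decision scores by the rank (Mann–Whitney)
formulation with half-credit for ties; per-fold ROC curves are undefined
when each fold holds out one patient. Group differences per feature use
the two-sided Mann–Whitney U test — robust for skewed radiomic features at
19-vs-83 group sizes — with raw p-values and a $p \le 0.05$ flag by
default and Holm correction behind an option, so the uncorrected and
corrected views are both one call away.

## The phantom generator

Real cohorts of pre-treatment breast MRI with expert ROIs are not freely
available, so the package ships a generator whose defaults encode the
cohort structure the analysis targets: 102 patients at 81%/19% R/NR
imbalance (83 vs 19), multi-slice elliptical tumors inside a breast-tissue
ellipse, and class-dependent texture. Each region (core, ~15-pixel
peritumoral band, remaining breast tissue) is a Gaussian random field:
white noise smoothed with a Gaussian kernel of scale `smoothing_sigma`
(pixels), standardized, then mapped to `mean_intensity ± intensity_sd`.
The single smoothing scalar monotonically controls GLCM contrast (down)
and homogeneity (up), which the test suite verifies over a sigma ladder —
that monotonicity is what makes parameter-recovery experiments clean.
Default core smoothing is 0.8 px for NR vs 2.5 px for R (rough,
disorganized non-responder cores), margin and background texture identical
across classes; moving the class gap into `margin_params` instead creates
the cohort used to test the margin-versus-core comparison. Rician-like
noise (the magnitude of the signal plus two independent Gaussian
perturbations, scale `noise_sigma = 10` against a tissue contrast of
roughly 100–220 units) mimics magnitude-MRI noise to first order, and
intensities are rounded to integers as scanner pipelines emit them.

Geometry: the tumor ellipse (semi-axes 8–14 px by default) is placed with
at least 15 px clearance to the breast boundary — checked exactly by
requiring the 15-px dilation to stay inside the breast mask, resampled up
to 25 times before failing — so every margin band fits in tissue. Slices
are generated independently; there is no through-slice texture continuity,
no anatomic realism, no freehand tumor shapes, and no scanner effects
beyond the noise model. Passing tests on phantoms therefore demonstrate
that the *pipeline* recovers planted statistical structure; they say
nothing about whether real tumors carry such structure.

The whole cohort is a pure function of its configuration, including the
seed: per-patient seeds are drawn once from the cohort seed, so records do
not depend on generation order.

## Numerical and degenerate-input behavior

* GLCM matrices satisfy $\sum P = 1$ to $10^{-9}$ and exact symmetry;
  implementation agreement with an exhaustive pair-enumeration oracle is
  required to $10^{-10}$ in the tests.
* An ROI with no valid pixel pair at distance $d$ raises an
  "insufficient pairs" error naming the cell rather than returning an
  empty matrix; an empty ROI fails at quantization.
* Feature maps (sliding-window feature images, default 5×5 window, window
  size otherwise unstated by convention) use the global ROI quantization
  range, not per-window ranges, so map values are comparable across the
  ROI; pixels with fewer than two valid pairs are `NA`.
* Grid cells in `run_experiment()` fail independently; a degenerate
  patient ROI logs an error for its cell and the rest of the grid
  completes. The run fails only if every cell fails.
* Feature tables round-trip through CSV at better than $10^{-12}$
  relative error (17 significant digits written).

## Problem sizes in the shipped tests

The test suite and acceptance script run phantom cohorts of 40 patients
(20 per class, 96×96 slices) for signal-recovery, null-control and
margin-signal experiments, 10-patient cohorts for pipeline plumbing, and
50 randomized ≤32×32 masked rasters for oracle equivalence — sizes chosen
so the full suite exercises every stage, including the 561-subset
exhaustive search, at desk scale. The 102-patient default configuration is
the intended scale for real experiments.

## Known limitations

* Only GLCM features: no grey run-length or size-zone matrices, no
  first-order histogram features.
* No DICOM ingestion, bias-field correction, registration, or cross-scanner
  intensity standardization; inputs are assumed comparable.
* Margins are pixel-unit, not millimeter-calibrated.
* The unnested feature-selection estimate is optimistic (see above); the
  null-control test bounds how optimistic it can be on signal-free data
  for a *fixed* configuration, not for the searched maximum.
* PNG slice input is codec-rescaled to [0, 1]; 16-bit TIFF and NIfTI
  round-trip exactly and are the formats the writers emit.
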