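---
title: "Multi-flavored feature extraction for prostate mpMRI grading: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-flavored feature extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tensorflavor)
```

## The pipeline

`tensorflavor` implements a *multi-flavored* (tensor) feature-extraction
pipeline for classifying prostate cancer Gleason grade groups (GG 1–5) from
multiparametric MRI. Each lesion is represented by four co-located regions
of interest (ROIs): T2W-transverse and T2W-sagittal (60×60 pixels at
0.5 mm), and DWI and ADC (15×15 pixels at 2 mm) — all spanning the same
30 mm around a ground-truth lesion point `(p, q, r)`. The pipeline:

1. normalizes each ROI to [0, 1] and resamples everything to a common
   60×60 grid;
2. fuses all C(4,2) = 6 unordered modality pairs with 8 pixel-level fusion
   algorithms, giving 4 originals + 48 fused = **52 flavor images** per
   patient;
3. extracts from every flavor **107 radiomics features** (18 first-order,
   14 shape, 24 GLCM, 14 GLDM, 5 NGTDM, 16 GLSZM, 16 GLRLM) and a
   **7200-long deep-feature vector** (the 32×15×15 bottleneck of a
   convolutional autoencoder);
4. assembles five feature sets — deep only (374 400 columns), radiomics
   only (5 564), per-flavor PCA on deep (52×5 = 260), global PCA on
   radiomics (107), and their concatenation (379 964);
5. preprocesses with SMOTE → standardization → PCA (sets 1, 3, 5) →
   correlation filter (|r| ≤ 0.8) → LASSO, and evaluates nine classifiers
   with stratified 5-fold cross-validation, reporting balanced accuracy and
   ROC/AUC as mean ± sd.

The reference cohort geometry is the PROSTATEx-2 training set (111
lesions; grade-group counts 36/40/20/8/7). Those images are external, so
the package ships a **phantom module** that generates synthetic cohorts
with exactly the study geometry and class structure, which is what all
tests and the acceptance script run on.

## The phantom model — what it emulates and what it does not

Each synthetic lesion is a stationary Gaussian random field (FFT-filtered
white noise) added inside an elliptical mask on top of a flat tissue
baseline, plus white acquisition noise everywhere. Two clinically
motivated grade effects are controlled by `signal_strength`:

* **mean ADC decreases strictly with grade group** (denser tissue diffuses
  less), with symmetric smaller effects on DWI (up) and T2W (down);
* **texture heterogeneity increases with grade**: the field's correlation
  length shrinks from 6 px (GG 1) to 2 px (GG 5) on the 60×60 grid, and
  its amplitude grows with grade.

All four modalities share one latent lesion field mixed with
modality-specific fields (70/30), so fusion has genuine shared structure
to exploit. DWI/ADC are obtained by block-averaging the 0.5 mm field to
the 2 mm grid before adding their own noise, mimicking the resolution gap.
At `signal_strength = 0` every grade dependency vanishes exactly, giving a
null model for permutation-style checks. Defaults (baselines 0.75/0.35/0.55,
ADC slope −0.08 per grade at strength 1, noise sd 0.04) were chosen once as
plausible normalized-intensity values; no per-grade intensity statistics
exist for the reference cohort, so these effect sizes are free parameters
of the phantom, not calibrated to real data.

What the phantom does **not** model: MR physics (bias fields, Rician
noise, partial volume), 3D lesion extent (single slice only), anatomical
context outside the lesion, inter-modality misregistration, and scanner
variability. Passing tests therefore demonstrate that the pipeline's
machinery is correct and can recover a known signal — not that it attains
any particular accuracy on clinical images.

## Fusion methods and numerical choices

All transform-domain methods run on a reflect-padded 64×64 grid (60 is not
divisible by 2^levels; 64 is), and the fused result is cropped back and
clipped to [0, 1] (clipped fraction is recorded per flavor and is < 5 % on
phantom data). Low-pass/approximation coefficients are averaged and
high-pass/detail coefficients combined by maximum absolute value — the
standard salience rule in pyramid/wavelet fusion — unless noted:

* **LP** — 4-level Laplacian pyramid (5-tap 1/16·[1 4 6 4 1] kernel).
* **RP** — 4-level ratio-of-low-pass (contrast) pyramid; ratio layers are
  fused by maximal deviation from 1 and guarded by ε = 10⁻⁶, removed
  exactly on reconstruction.
* **DWT** — 3-level decimated orthonormal db2 transform with
  periodization; implemented as orthogonal analysis matrices, so perfect
  reconstruction is exact by construction.
* **WAVELET** — the pipeline treats "wavelet fusion" as distinct from DWT:
  a 2-level *stationary* (undecimated) db2 transform with the average rule
  on all bands, yielding a shift-invariant, smoother fusion.
* **DTCWT** — a dual tree of two perfectly-reconstructing orthonormal
  wavelet banks (db2 / db3); the two trees' detail coefficients are
  treated as real/imaginary parts and selected jointly by complex
  magnitude, reconstruction averages the trees. This keeps the defining
  dual-tree property (approximate shift invariance through paired trees)
  with filters that are exactly orthonormal.
* **CVT** — an FFT-based directional multiscale transform: the frequency
  plane is partitioned (exactly, into a partition of unity) into a radial
  low-pass, 3 annular scales and 8 paired angular wedges per scale; band
  images are real and sum back to the input to machine precision.
  Curvelet-style directional selectivity with exact invertibility.
* **WEIGHTED** — fixed convex combination, default (0.5, 0.5).
* **PCA** — weights from the leading eigenvector of the 2×2 covariance of
  the flattened pair (absolute components, normalized to sum 1); a
  degenerate covariance falls back to (0.5, 0.5).

Identity (`fuse(x, x) = x`) holds to 1e-6 for every average/max-rule
method (1e-3 for CVT) because every backend reconstructs perfectly.

## Radiomics extractor

The 107-feature contract (names, 7-class partition, counts) follows the
field-standard default feature set; formulas follow IBSI definitions. The
extractor is 2D single-slice: texture matrices use the 4 planar directions
(GLCM distance 1, symmetric, features averaged over angles; GLSZM zones and
GLDM/NGTDM neighbourhoods 8-connected), and shape descriptors treat the
mask as a one-slice volume of 3 mm thickness — in-plane area and perimeter
come from a marching-squares contour of the mask, principal axes from the
eigenvalues of the physical coordinate covariance. The least (out-of-plane)
axis of a single slice is 0 by convention, as is Flatness.

Normalized images are rescaled to [0, 255] and discretized with fixed bin
width 25 from the masked minimum (byte-range binning). Degenerate inputs
are defined by limits — a constant masked region has Variance 0, Entropy
0, GLCM Correlation 1 — and the extractor never emits NaN. The lesion mask
defined on the T2W grid is reused (nearest-neighbour) for all 52 flavors.

## Autoencoder

Encoder: conv(16, 3×3, stride 2) → conv(32, 3×3) → maxpool(2×2) →
conv(32, 3×3), ReLU throughout, bottleneck 32×15×15 = 7200. Decoder: two
stride-2 transposed convolutions (16, then 8 filters) and a final 3×3
convolution with sigmoid, output 60×60. Only the layer types and the two
boundary shapes are externally constrained; the filter counts and 3×3
kernels are the minimal standard architecture satisfying both, and are a
design choice of this package. The objective is J = ½ Σ (y − x)²,
minimized by Adam (lr 10⁻³, batch 32 by default) on exact hand-derived
gradients (the test suite checks them against finite differences).
Training is unsupervised on pooled flavors of all patients; labels are
never seen. Optional k-fold monitoring (patience 10) records validation
objectives; the returned model is always retrained on all images. Deep
features are the flattened ReLU bottleneck (channel slowest, then row,
then column), hence nonnegative.

## Preprocessing and evaluation

The chain is smote → standardize → pca → correlation_filter → lasso, in
that order. Standardization uses the population convention (divide by n).
The preprocessing PCA (sets 1, 3, 5) keeps components explaining 95 % of
training variance, capped at n − 1. The correlation filter scans columns
in fixed order and drops the later member of any pair with |r| > 0.8;
constant columns correlate 0 by convention. LASSO is an L1-penalized
logistic model (grouped multinomial for the five-group scheme) with the
penalty chosen by cross-validated deviance; an empty selection falls back
to the previous step's columns. Set 3's 260 columns are 52 flavors × 5
per-flavor PCA components; set 4's 107 columns are one global PCA of the
radiomics matrix (107 is not divisible by 52, so a per-flavor reading is
arithmetically impossible).

**Fold safety.** By default every statistic above — including SMOTE — is
fitted on each fold's training split only; synthetic samples never enter
a test split. `leaky_mode = TRUE` reproduces the global
preprocessing-before-CV protocol for comparison; on phantom data it is, as
expected, at least as optimistic as the fold-safe protocol. Making leakage
explicit rather than default is a deliberate design decision.

Labels default to the clinically standard binary target (GG 1, clinically
insignificant, vs GG ≥ 2); `scheme = "gg5"` switches to the five grade
groups (macro one-vs-rest AUC; balanced accuracy generalizes natively).
Whether SMOTE ran inside or before CV, and whether the target was binary
or five-class, are not externally specified; the package provides both
modes rather than asserting one.

Classifiers: L2 logistic regression (C ∈ {0.1, 1, 10}), RBF-SVM (C ∈
{0.1, 1, 10}), Gaussian naive Bayes, k-NN (k ∈ {3, 5, 7}), random forest
(200 trees, depth ∈ {∞, 8}), bagged decision trees (50 bootstrap CART
trees), gradient boosting (200 rounds, learning rate ∈ {0.05, 0.1}), and
two soft-voting ensembles: Voting 1 = {logreg, SVM, GNB, kNN, RF,
bagging}, Voting 2 = {gradient boosting, SVM, extra-trees}. Grids are
deliberately small; hyperparameters are tuned by nested 3-fold balanced
accuracy inside each outer fold. Voting members use fixed mid-grid
defaults (tuning six members inside every fold is disproportionate, and
probability-averaged voting is used because AUC must be defined for the
ensembles; both are package decisions). The voting ensembles are evaluated
with the same 5-fold protocol as the base classifiers so that mean ± sd is
defined uniformly. All randomness flows from one master seed through
labelled sub-seeds (`derive_seed`), making every result reproducible
bit-for-bit.

## Problem sizes used by the shipped checks

The test suite and acceptance script run entirely on phantoms, at sizes
chosen to exercise every contract while staying desk-scale: structural
checks on a 40-patient high-signal cohort (signal strength 3, class counts
13/15/7/3/2); the feature-set width check on the full 111-patient cohort
with the study class counts, with the autoencoder trained for 2 epochs on
a 208-image subsample (widths are architecture properties and do not
depend on training length); signal recovery with random forests over 3
seeds and permutation nulls over 6 seeds; the autoencoder capacity check
on 8 images for 500 epochs (batch 2, lr 3·10⁻³).

## Known limitations

* Single-slice 2D only; no 3D texture or shape.
* NIfTI-1 input only; DICOM series must be converted upstream.
* The curvelet-style backend is a self-contained FFT directional pyramid,
  not a wrapped fast discrete curvelet transform; its wedges are
  piecewise-linear rather than parabolic-scaling curvelet windows.
* The radiomics extractor follows IBSI formulas but is not IBSI-certified;
  exact numeric agreement with other engines' implementation details
  (e.g. mesh algorithms) is not claimed — the contract is the feature
  names, partition, determinism and limit behaviour.
* Phantom effect sizes are free parameters; reported phantom AUCs
  characterize the pipeline, not clinical performance.
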