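---
title: "Peritumoral radiomics on mammography: models, phantom and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peritumoral radiomics on mammography: models, phantom and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perirad)
```

## The scientific question

Malignant breast tumours remodel the stroma immediately around them, and
those changes are visible — weakly — on mammograms as altered texture in the
tissue just outside the delineated mass. `perirad` asks the operational
question: *does adding peritumoral image features to tumoral ones improve
benign/malignant discrimination of non-spiculated, noncalcified masses
(NSNCM), and at which physical distance?* The pipeline compares eleven
region models — the tumour itself, the peritumoral ring at 1–5 mm, and the
combined (tumour + ring) region at 1–5 mm — under identical feature
extraction, feature selection, classification and cross-validation, and
tests the paired AUC differences with DeLong's method.

Because clinical mammograms of this kind are not publicly available, the
package is driven by a synthetic phantom whose class signal is *known and
placed by construction*: every downstream claim the test suite makes is a
claim about recovering injected signal, not about real tissue.

## Region construction

The tumour mask is taken as given (on real data it would be a radiologist
contour; the phantom supplies ground truth). For a distance $d$ the package
computes

* the dilation $D_d$ of the mask: all pixels within Euclidean distance
  $d$ mm of the mask, computed with an elliptical structuring element whose
  support is exactly the offsets within $d$ under the image's (possibly
  anisotropic) pixel spacing — equivalent to thresholding the Euclidean
  distance transform;
* the body mask: Otsu threshold on the intensity histogram, components
  smaller than 0.5 % of the image discarded, holes filled. The pectoral
  muscle is kept deliberately; only air background is removed;
* the ring $(D_d \setminus T) \cap B$ and the combined region
  $(D_d \cap B) \cup T$. Tumour pixels are retained even where the automatic
  body mask disagrees, resolving that tie in favour of the human contour.

A numerical note: the discrete ring of a few-pixel-thin annulus is
systematically *thinner* than its analytic counterpart, because distances
are measured to mask pixel centres. At 1 mm/px a 3 mm ring around a 10 px
disk is about 6 % under the analytic area; at mammographic spacings
(≤ 0.5 mm/px) the deficit falls to ~3 %. Tests therefore check the analytic
annulus at 0.5 mm/px and check the dilation operator itself against
brute-force distance enumeration, where agreement is exact.

## The feature engine

`extract_all()` computes 97 features per (image, mask) pair in six
families: 18 first-order statistics, 9 two-dimensional shape descriptors,
and the four gray-level texture families — co-occurrence (GLCM, 24),
run length (GLRLM, 16), size zone (GLSZM, 16) and dependence (GLDM, 14) —
with IBSI-consistent definitions, log base 2, and explicit conventions
where the standards leave room:

* **Discretization** — fixed bin width, default 25 intensity units
  (`feature_config()`), mapping $v \mapsto \lfloor (v - \min v)/w \rfloor + 1$.
  A fixed bin count is available. Entropy and uniformity of the first-order
  family use this same histogram.
* **GLCM** — symmetric matrices at distance 1 for the four 2-D angles,
  normalized per angle; features are averaged over angles (not computed on a
  merged matrix). A single-pixel mask has no pairs and yields an `NA` vector
  flagged by a warning rather than a fabricated value.
* **GLRLM** — runs counted in the four directions and feature-averaged.
* **GLSZM** — zones are 8-connected components of equal level.
* **GLDM** — dependence of a pixel is 1 (itself) plus the number of
  8-neighbours inside the mask with the same level (cutoff $\alpha = 0$).
* **Moments** use the population ($N$) denominator; kurtosis is not
  excess-corrected; the perimeter is the total length of exposed pixel
  edges, exact for axis-aligned rectangles; axis lengths are the
  $4\sqrt{\lambda}$ ellipse convention from the pixel-centre covariance.

Toolbox pipelines that multiply these families by wavelet/LoG-filtered
image channels report feature counts in the hundreds; such counts depend
entirely on the filter-bank and bin settings, so this engine records its
own manifest (`feature_names()`) instead of targeting any particular
number.
Every matrix family is verified against an independent brute-force
implementation (explicit pixel loops) on random regions to $10^{-9}$.

## Classification stack

Per region model and per cross-validation rotation, strictly inside the
training folds:

1. **Correlation filter** — offending pairs ($|r| > 0.9$ Pearson) are
   resolved greedily in descending $|r|$ (lexicographic tie-break), dropping
   the member with the smaller absolute point-biserial correlation with the
   label; a constant feature has relevance 0. The result is idempotent and
   deterministic.
2. **L1-penalised logistic regression** (glmnet) on train-standardized
   features; the penalty is chosen from $\{0.01, 0.1, 1, 10\}$ by
   validation-fold AUC, ties toward the stronger penalty.
3. The operating threshold maximizes Youden's $J$ on the validation fold;
   sensitivity/specificity are then read off the test fold.

Cross-validation is five-fold and stratified *by patient* — both views of a
patient travel together, otherwise near-duplicate views leak across the
split. Each rotation uses three folds for training, one for validation
(penalty and threshold choice) and one for testing, rotating the test fold
so every patient is tested exactly once. Reported AUCs are the mean of the
five test folds; confidence intervals and the paired tumoral-vs-other
DeLong tests use the pooled out-of-fold scores. Patient-level scores take
the maximum over a patient's views (the most-suspicious-view reading);
`mean`/`min` are available.

## DeLong inference

`delong_test()` implements the structural-components algorithm with
midranks: placements $V_{10}, V_{01}$ per positive/negative case, sample
covariances of paired components, a two-sided normal $p$. Degenerate
variance (model compared with itself; two perfect models) reports $z = 0$,
$p = 1$ with a flag rather than `NaN`. The implementation is cross-checked
in the tests against brute-force $\psi$-function loops and against pROC.

## The phantom

`generate_dataset()` emulates only what the downstream stages exercise:

* two views (CC/MLO) per patient, one elliptical mass per patient placed
  fully inside a bright half-elliptical breast on a dark noisy background;
  MLO views add a pectoral wedge so the body-mask rule (keep muscle, drop
  air) is actually exercised;
* smooth low-frequency parenchyma texture plus i.i.d. Gaussian pixel noise
  (`noise_sd`, default 20 intensity units);
* class signal injected as *extra variance*: malignant lesions receive
  additional zero-mean noise of standard deviation `core_effect * noise_sd`
  inside the mass and `rim_effect * noise_sd` in the exact-distance annulus
  of width `rim_width_mm` (default 2 mm). The injected per-pixel variance
  margin is therefore $(e \cdot \sigma)^2$ — a quantity the tests recover
  from pixel statistics. Variance rather than mean shift is used so that
  the GLCM-family features, not just first-order means, carry signal.

**Calibration.** The canonical signal conditions used by the test suite and
the acceptance script are `core_effect = 0.25`, `rim_effect = 0.30` at
`noise_sd = 20`. They were calibrated once so that the tumoral-only
radiomics model operates in the clinically typical range (patient-level
AUC ≈ 0.78 at 200 patients) instead of saturating: with effects ≥ 0.5 every
region model is perfect and region comparisons become uninformative. The
defaults of `phantom_config()` are a *null* phantom (both effects 0), under
which the whole pipeline must score at chance — the suite asserts AUC ∈
[0.4, 0.6] for all eleven models at 200 patients, and a patient-coherent
label permutation of a signal-bearing cohort must do the same (leakage
guard).

What the phantom does **not** model: compression deformation, scatter,
vessel/ligament structure, spiculation, calcifications, BI-RADS density
strata, or any photometric realism. Passing tests therefore demonstrate
that the *pipeline* recovers known signal with correct geometry and honest
cross-validation — they say nothing about effect sizes in real mammograms.

**Problem sizes.** The signal-recovery property uses five cohorts of 200
patients (400 views) at 192 × 192 px, 0.25 mm/px, masses of 3–7 mm radius;
the chance-band and leakage checks use 200 and 100 patients. These sizes
put AUC sampling noise (≈ 0.03–0.04 s.d. at chance) comfortably inside the
asserted bands while keeping a full suite run on one CPU in minutes.

## The reduced-scale CNN

The full-scale configuration (`cnn_config(architecture = "resnet34")`)
documents the standard recipe — 256 × 256 inputs, ImageNet-pretrained
ResNet-34, SGD momentum 0.9, lr 0.001, weight decay 1e-5, factor-0.1 drop
after a 10-epoch validation plateau, 100 epochs, batch 64, flip
augmentation — but is configuration only: no deep-learning backend is a
dependency of this package. The trainable `"tiny"` variant keeps the entire
training-loop contract (minibatch SGD with momentum and weight decay, flip
augmentation, plateau schedule, binary cross-entropy) on an architecture
small enough for in-package backpropagation: two 3 × 3 conv/ReLU/mean-pool
stages, global average pooling, batch normalization of the pooled features,
and a sigmoid head. Design notes:

* **Batch normalization of the pooled features** is load-bearing, not
  cosmetic: region-masked crops give pooled features with a large common
  offset (condition number ~10⁴ for the head), and plain SGD cannot fit
  them within 100 epochs. Batch statistics are used during training and
  recalibrated on the clean training images afterwards, the usual BN
  practice.
* **Class activation maps.** `cnn_cam()` upsamples the head-weighted sum of
  the final conv maps and min-max normalizes to [0, 1]. Two refinements
  make the map a stable localization of evidence: the activations of an
  all-zero input are subtracted first (trained conv biases otherwise give
  empty background a constant response), and the *magnitude* of the weighted
  sum is mapped by default — with a single sigmoid output the sign with
  which an informative channel enters the head is arbitrary, so the signed
  map (available via `signed = TRUE`) can invert between equally good
  fits.
* The localization property (more CAM mass inside the combined region than
  outside) is asserted for a model trained on the full crop set, which has
  to exploit the injected texture signal; a 16-image overfit — used for the
  separate capacity check — may legitimately memorize region outlines
  instead.
* Gradients are verified against central finite differences, including
  differentiation through the batch statistics.

## Clinical statistics

`chi_square()` applies Pearson's statistic to benign/malignant r × 2 count
tables with the Yates continuity correction for 2 × 2 tables only — the
convention that reproduces the published cohort's printed values (the
uncorrected 2 × 2 statistic differs by ~1); `clinical_table1_counts()`
ships the published age/size/composition tables, with the empty
age ≤ 20/malignant cell as a structural zero. `two_sample_t()` is the
pooled-variance two-sided t test with an explicit zero-variance convention
($t = 0, p = 1$ for identical constant samples).

## Orchestration and reproducibility

`study_config()` bundles all stage configurations; it round-trips through
YAML and its FNV-1a hash is stamped into a provenance JSON next to every
stage output. `study_simulate()` → `study_extract()` → `study_evaluate()` →
`study_compare()` / `study_report()` form a file-based pipeline in which
each stage refuses to run on outputs produced under a different
configuration hash, and re-running a stage with the same seed reproduces
its CSVs byte for byte. A thin command-line wrapper over these functions is
installed under `inst/cli/perirad.R`. All randomness flows from explicit
seeds; stage-specific streams are derived deterministically so that, e.g.,
the CV plan does not perturb phantom generation.

## Known limitations

* Phantom realism is deliberately minimal (see above); absolute AUC values
  on the phantom have no clinical meaning, only their ordering under
  injected signal does.
* Ring geometry is resolution-limited for rings only a few pixels thick.
* The feature engine is 2-D only and implements no wavelet/LoG filter
  banks, so its manifest (97 features) is smaller than toolbox
  configurations that multiply feature classes by filtered channels.
* The tiny CNN is a contract-faithful stand-in at desk scale; its absolute
  performance is not comparable to a pretrained deep network.
* Subgroup analyses on the phantom are limited to mass size; age and
  breast-composition strata exist only where such metadata accompany real
  images.
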