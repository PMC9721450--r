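# perirad

Does the tissue immediately *around* a breast mass help a classifier decide
whether the mass is malignant? For non-spiculated, noncalcified masses
(NSNCM) on mammography — the ones without the classic malignancy give-aways —
the question matters clinically, and answering it requires comparing, under
identical conditions, models built from the tumoral region, from
peritumoral rings at physical distances of 1–5 mm, and from their union.

`perirad` is an R implementation of that whole comparison as a tested,
reusable pipeline:

* **Region construction** — Otsu body mask (breast + pectoral muscle),
  exact Euclidean-distance dilation in millimetres, ring
  `(dilate(T, d) \ T) ∩ body` and combined `(dilate(T, d) ∩ body) ∪ T`
  regions for d = 1…5 mm.
* **A from-scratch 2-D radiomics engine** — 97 features per region in six
  families (first-order, shape, GLCM, GLRLM, GLSZM, GLDM), every
  matrix-based feature verified against brute-force oracles to 1e-9.
* **The classifier stack** — correlation filter (|r| > 0.9, keep the more
  label-relevant member) followed by L1-penalised logistic regression, with
  the penalty picked by validation AUC.
* **Honest evaluation** — patient-stratified five-fold 3:1:1
  cross-validation (both views of a patient travel together), ROI-level and
  patient-level scoring (max over views), AUC with DeLong confidence
  intervals, Youden operating points, and paired DeLong tests of every
  region model against the tumoral reference.
* **Clinical table statistics** — Pearson chi-square on r×2
  benign/malignant count tables (Yates-corrected for 2×2) and the pooled
  two-sample t test, with the published cohort's count tables included.
* **A reduced-scale CNN** — a tiny two-stage convolutional network with the
  full training-loop contract (SGD + momentum, flip augmentation, plateau
  learning-rate schedule) and class activation maps, trained by in-package
  backpropagation.
* **A synthetic phantom** — since clinical NSNCM data are private, a
  generator produces two-view mammogram-like images with one elliptical
  mass per patient and *known* texture signal injected independently into
  the mass core and a peritumoral rim, so that every pipeline stage is
  testable against ground truth.

The statistic at the core of the region comparison is the paired DeLong
test: for models A and B scored on the same cases, with placement
components V₁₀, V₀₁ per case,

    z = (AUC_A − AUC_B) / sqrt(S₁₀[1,1]/m + S₁₀[2,2]/m − 2S₁₀[1,2]/m + …)

with S the sample covariances of the paired components; `perirad`
implements the midrank (fast) formulation and cross-checks it against pROC.

## A worked example

```r
library(perirad)

# 60 patients, texture signal in the mass core and the 2 mm rim
cfg <- phantom_config(n_patients = 60, core_effect = 0.25, rim_effect = 0.30,
                      seed = 11)
ds  <- generate_dataset(cfg)
res <- run_study(ds, distances_mm = 2, seed = 11)
print(res)
```

```
perirad_study: patient-level summary
       region distance_mm   auc ci_lo ci_hi sensitivity specificity n_pos n_neg
1     tumoral          NA 0.783 0.648 0.903           1       0.500    30    30
2 peritumoral           2 0.961 0.896 0.997           1       0.667    30    30
3    combined           2 0.906 0.828 0.989           1       0.633    30    30
  p_vs_tumoral
1           NA
2       0.0107
3       0.0115
```

Reading it: the tumoral-only radiomics model scores a patient-level AUC of
0.783 (mean of the five test folds; the CI comes from DeLong on the pooled
out-of-fold scores). Adding the 2 mm peritumoral ring raises the AUC to
0.906 for the combined region, and the paired DeLong test against the
tumoral model gives p = 0.012 — the pipeline recovers the rim signal that
the phantom injected. On a null phantom (`core_effect = 0, rim_effect = 0`)
every model scores at chance.

The published cohort's clinical tables are also reproducible directly:

```r
chi_square(clinical_table1_counts()$size)
#> chi-square = 61.7 (df = 1, Yates-corrected), p = 3.998e-15
```

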