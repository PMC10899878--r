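---
title: "Methods: VAE augmentation of spinal posture data"
author: "postureVAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VAE augmentation of spinal posture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(postureVAE)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open. Nothing here reports an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The data model

A posture sample is a 54-vector in degrees: three pelvic angles and the
orientation of 17 vertebral levels (VP, T1–T12, L1–L4) in the sagittal,
coronal and transverse planes. `PostureExperiment` stores samples as
columns of a `SummarizedExperiment` with per-sample `subject_id`,
`class_label` and `session_idx`. Subjects — not samples — are the unit of
every split: repeated sessions of one subject are strongly correlated, and
letting them straddle a train/test boundary would overstate generalization
to new subjects.

## 2. The synthetic cohort generator

Real surface-topography cohorts of this kind are not publicly deposited,
so the package ships a generator whose draws play the role of the study
population. Its structure, per anatomical plane:

* **Population baseline** — a fixed smooth sagittal profile (amplitude
  ~12°, the kyphosis/lordosis alternation) plus a typical pelvic
  inclination of 18°; coronal and transverse baselines are neutral.
* **Class effects** — each of the five classes (healthy_1 201, healthy_2
  25, back_pain 32, spinal_fusion 34, osteoarthritis 60 subjects) shifts
  the mean curve by a smooth expansion in the first 4 cosine basis
  functions over the 17 levels, coefficient scale `classShiftScale`.
* **Subject effects** — each subject draws a 10-dimensional standard
  normal factor score; smooth loading curves map it to the 51 vertebral
  features and a linear map to the 3 pelvic ones, scaled so the implied
  per-feature SD is `subjectSd`. Loading columns decay geometrically
  (`factorSdDecay = 0.75`), giving the scree-like eigenvalue spectrum real
  posture data show; the top 7 factors carry ~98% of the factor variance,
  so bottlenecks of 7–15 dimensions can in principle capture the
  between-subject structure.
* **Session noise** — i.i.d. Gaussian, SD `sessionSd`, per feature.

Defaults: 12 sessions/subject, `subjectSd` 3°, `sessionSd` 1°,
`classShiftScale` 0.5°. The SD ordering (session < class shift influence <
subject) encodes two study conditions: repeated measures cluster by
subject, and classes overlap heavily. `classShiftScale` was calibrated
once against the generator's own weak-separation contract — a grouped
10-NN classifier on class labels must stay below twice uniform chance in
balanced accuracy. We use *balanced* accuracy because with a 57% majority
class, plain accuracy reflects the prior, not class signal; at the default
the measured balanced accuracy is 0.38 (< 0.4) while plain accuracy equals
the majority rate, i.e. there is no exploitable class structure — the
generator's analogue of a latent space with no visible class clusters.

What the generator does **not** emulate: biomechanical coupling between
levels beyond smoothness, asymmetric or skewed pathology effects,
measurement drift between sessions, and any covariance difference between
classes (class effects are pure mean shifts). Tests passing on this cohort
therefore show the pipeline behaves correctly under the assumed structure,
not that the VAE reproduces every property of clinical data.

## 3. The VAE

Architecture 54 → 256 → 108 → (μ, log σ²) of dimension 15; symmetric
decoder with a linear output layer; ReLU elsewhere. Training: Adam
(lr 0.001, β₁ 0.9, β₂ 0.999), batch 128, exactly 400 epochs (no early
stopping), He-uniform initialization, all seeded.

**Loss scale.** The optimized objective is the negative ELBO of a
unit-variance Gaussian observation model: the squared reconstruction error
*summed over the 54 features* (averaged over the batch) plus the closed-form
KL divergence (summed over latent dimensions, averaged over the batch),
`klWeight = 1`. This convention matters: averaging the reconstruction over
features as well would multiply the effective KL weight by 54 and collapse
the posterior — we verified this variant reconstructs nothing but the mean.
Reported reconstruction errors are always *per-entry* MSE in scaled
(z-scored) units, and are computed on the deterministic path `x̂ =
decode(μ(x))`, so a reported MSE is reproducible and free of sampling
noise. The log-variance head is clamped to [−10, 10] for numerical safety;
`lvBiasInit` exposes the head's initial bias (default 0 — tighter initial
posteriors were tried and made no measurable difference on this data).

**Known limitation.** A VAE trained with this (standard) likelihood scale
under-disperses: at the ELBO optimum the deterministic decoder cannot emit
the ~0.5 per-feature variance the unit-variance likelihood absorbs, so
prior samples carry less variance than the data. On the default cohort the
generated-sample covariance sits at Frobenius distance ≈ 0.49 ×
its own norm bound (inside the 0.5 tolerance the tests assert) and ~3.8×
closer to the data covariance than a white-noise generator. This is a
property of the objective, not an optimization failure; it is why the 10-NN
discriminability is ~0.55–0.65 rather than exactly 0.5.

## 4. Indistinguishability arms

* **kNN** — `class::knn` (Euclidean, uniform vote, k = 10) under
  stratified shuffled 5-fold CV in the same scaled space the VAE trains in
  (the natural space; the choice is configurable by standardizing or not
  before the call). Equal group sizes are expected; imbalance warns.
* **SPM** — at each of the 17 levels the pooled-variance two-sample t
  statistic; family-wise control by permuting group labels and taking the
  (1−α) quantile of max |t| as the critical threshold t\*. Two-tailed by
  construction. When C(nA+nB, nA) ≤ the permutation budget the null is
  enumerated exhaustively (then seed-independent). Nodes with identical
  values in both groups get t = 0. The threshold uses the order statistic
  at ⌈(1−α)B⌉ without including the observed labeling, giving exceedance
  probability B(1−α)/(B+1) ≈ α; the test suite verifies calibration
  empirically (pooled 1500 null replicates within the 95% Monte-Carlo
  band). Per-plane analyses draw one sample per subject so curves are
  independent, and subsample the synthetic pool to the same size.
* **Rater arithmetic** — confusion-matrix accuracy, the loose majority
  vote (an item is "real" when its real-vote fraction ≥ threshold, ties
  permissive — with three raters and binary votes ties cannot occur, so
  the rule only matters for even panels), and Fleiss' κ with the standard
  pooled-proportion chance correction. Collecting human ratings is out of
  scope; `exportBlindedRatingSheet` produces the blinded sheets.

## 5. The autoencoder benchmark

AE 54 → 500 → 250 → 50 → latent (linear) with mirrored decoder, linear
output, ReLU elsewhere; Adam lr 0.001, batch 64; early stopping on
validation MSE with patience 10, cap 1000 epochs, best-validation weights
restored (the returned validation MSE is exactly the minimum of the
recorded history — an invariant the tests assert).

Schemes: RTD (real only), RTSD (+1× synthetic), RT3SD (+3× synthetic),
synthetic rows generated in scaled space by the fold's own VAE. Using the
fold's own VAE (rather than one shared VAE picked across folds) avoids
test subjects leaking into the generator; the shared-VAE variant can be
reproduced by passing the same VAE per fold explicitly. Train MSE is
reported on the real training rows only, so the column is commensurable
across schemes; validation sets contain real rows only, and the
standardizer is always fitted on real training rows.

**Replicated data-scarce comparison.** `augmentationReplicates()` runs 10
seeded replicates; each draws its own grouped 5-fold split, keeps fold 1,
subsamples the real training rows to 150 (re-fitting the standardizer on
those rows), trains the VAE and one AE per scheme × latent dimension, and
scores real-test MSE. One fold per replicate keeps the replicate — not the
fold — as the unit of the sign test while holding the total at 10 VAE and
40 AE trainings, which completes on one CPU in a few minutes. The test
suite asserts the two directional findings on this design: augmentation
(RTSD, dim 15) beats real-only training in at least 8 of 10 replicates,
and the augmented 7-dimensional bottleneck matches the unaugmented
15-dimensional model in at least 7 of 10.

## 6. Other numerical choices

* Standardization uses the population (divide-by-n) SD; zero-variance
  features transform to 0 and invert to the training mean.
* The isolation forest grows 500 trees on subsamples of 256 with depth cap
  ⌈log₂ ψ⌉; a numeric contamination c removes exactly round(c·n) highest
  scores (an outcome-matched filter), `"auto"` removes scores above 0.5.
  Session selection runs before outlier filtering.
* Subject partitioning shuffles the subject list under the seed and deals
  round-robin, so test-set sizes differ by at most one; the validation
  fraction (0.125 of non-test subjects) yields ≈70/10/20 overall at k = 5.
* Stage seeds derive from the global seed by a 31-based string hash mixed
  with a Lehmer multiplier, always inside 32-bit range.
* Degenerate inputs fail loudly: subjects with too few sessions are named;
  an all-one-category rating table is an error (κ undefined), not NaN.

## 7. Scope limits

No GAN or conditional-VAE baselines, no physics-informed constraints, no
UMAP computation in-core (latent embeddings are exported as tables), no
parametric (random-field) SPM thresholds, and no stratification of folds
by class. The hyperparameter grids that once selected the shipped
architectures are provided only as ordinary arguments — the final
configurations are taken as given.
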