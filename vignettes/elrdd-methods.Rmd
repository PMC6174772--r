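---
title: "Ensemble logistic regression over speech-feature subspaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble logistic regression over speech-feature subspaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elrdd)
```

## The model

The object of study is a per-recording acoustic feature vector of 1992
features in four categories — MFCC (630), prosodic (952), spectral (378)
and glottal (32) — extracted from short speech recordings of depressed
patients (label 1) and healthy controls (label 0). Rather than training a
single classifier on all 1992 columns, the ensemble trains one logistic
regression per *category-combination subspace*: every non-empty subset of
the four categories, K = 2⁴ − 1 = 15 subspaces in all. Because the
categories are produced by very different extraction methods, the
subspaces are diverse by construction, and each is far lower-dimensional
than the full space.

Each base pipeline is: select the subspace columns → standardize
(train-set column mean/sd) → locally linear embedding to d dimensions →
logistic regression on the embedded coordinates, fitted by maximizing

$$\ell(w) = \sum_i \left[ y_i (w \cdot z_i) - \log(1 + e^{w \cdot z_i}) \right] - \frac{\lambda}{2}\lVert w_{\setminus \text{intercept}} \rVert^2 .$$

A recording is scored by summing the per-subspace class-1 probabilities,
$s_1 = \sum_k \sigma(w^{(k)} \cdot x^{(k)})$, and the complementary
class-0 probabilities $s_0 = \sum_k (1 - \sigma(\cdot))$, so that
$s_1 + s_0 = K$ identically — a conservation law the tests assert on
random inputs. The recording-level call thresholds $s_1/K$ at τ; the
subject-level call (the "-E" extension) sums $s_1$ and $s_0$ over all of a
subject's recordings and calls depressed when $S_1 \ge S_0$.

Assumptions worth stating: recordings of one subject share the subject's
label and are treated as exchangeable at fusion time; the class signal is
assumed to survive an unsupervised, label-blind dimensionality reduction;
and the probability sums treat the 15 base classifiers as equally
trustworthy (no per-subspace weighting).

## Tunable parameters

* `knn` (default 12) — LLE neighbour count. Must exceed the embedding
  dimension for locally faithful barycentric reconstruction; 12 is a
  conventional middle value for sample sizes in the hundreds-to-thousands
  range. Neighbour ties are broken by lowest training index.
* `dim` (default `min(30, n_train − 2)`) — embedding dimension, the
  number of logistic predictors per base classifier. The cap at 30 keeps
  the logistic fits well-conditioned at small n.
* `lambda` (default 1) — ridge penalty on the non-intercept logistic
  weights. The embedded training classes can be linearly separable, where
  the unpenalized maximum-likelihood estimate diverges; any λ > 0
  guarantees a finite maximizer. `lambda = 0` recovers the plain
  maximum-likelihood fit.
* `threshold` τ (default 0.5) — recording-level decision threshold on
  s1/K. Ties classify as depressed at both granularities: in a screening
  setting the costlier error is the missed patient, so the knife-edge case
  goes to sensitivity.
* `fusion` (default `"prob_sum"`) — subject-level rule. `"majority"`
  (vote over per-recording labels) is provided for comparison; the two
  disagree on constructed score patterns (a strong minority of confident
  recordings can carry the probability sum), which the tests enumerate.
* `genderMode` — males and females are modelled independently by default
  (gender-dependent modelling); a combined mode exists and is what the
  scaled-down simulation suites use, since their per-gender cells are
  small.

## Numerical choices

*Standardization.* Population (1/n) standard deviations, floored at 1e-8;
a constant column therefore maps to exactly zero after centering rather
than to 0/0.

*LLE weight systems.* For each point, the barycentric weights over its
k nearest neighbours solve the local Gram system C w ∝ 1 with a ridge on
the diagonal. The ridge is adaptive: the conventional `tr(C)·1e-3/k` when
C is numerically full rank, but a vanishing `tr(C)·1e-12` when C is rank
deficient. Rank deficiency is precisely the situation where an exact
affine reconstruction of the point from its neighbours exists (duplicate
points, data on a low-dimensional affine subspace), and the vanishing
ridge lets the solution collapse onto it: a duplicated point takes its
twin's embedding exactly, data on a d-dimensional affine subspace are
reconstructed with residuals at numerical zero, and the out-of-sample
transform of a training point reproduces its training coordinates. A
fixed large ridge would smear weight across all neighbours and break all
three properties at the 1e-2 level.

*Embedding.* The coordinates are eigenvectors of M = (I−W)ᵀ(I−W) for the
d smallest eigenvalues after deflating the trivial constant direction.
The deflation is explicit — M has the constant vector as an exact
eigenvector with eigenvalue 0, and a rank-one shift `(tr(M)+1)/n · 11ᵀ`
lifts it above the spectrum of interest without touching the orthogonal
complement. This matters on degenerate (exactly low-dimensional) data,
where "drop the single smallest eigenvector" can pick a rotation that
mixes the constant into the kept coordinates. Each coordinate is centered,
scaled to unit variance over the training points, and sign-fixed by making
its largest-magnitude loading positive, so results are reproducible across
linear-algebra backends.

*Out-of-sample extension.* The method's source formulation trains the
embedding but does not say how test recordings are projected. The package
uses the standard nonparametric neighbour-weight extension: find the new
point's k nearest training points, solve the same weight system, and take
the weight-combination of those points' training coordinates. It is
deterministic and consistent with the fit (transforming the training set
reproduces the training embedding).

*Logistic optimization.* Newton–Raphson on the penalized likelihood with
step halving (up to 30 halvings per iteration) and a gradient-direction
fallback if the Hessian solve fails; convergence at gradient ∞-norm
< 1e-8, cap at 200 iterations with the best iterate returned under a
warning. The intercept is implemented as an appended constant-1 coordinate
— the score formulation writes a bare inner product, and absorbing the
intercept into the weight vector keeps that notation while letting
class-imbalanced fits move their base rate; the intercept is never
penalized.

*ANOVA and LSD.* The one-way F test is delegated to
`stats::oneway.test(var.equal = TRUE)`; the LSD post-hoc t statistics use
the pooled within-group mean square and its N − g degrees of freedom,
so in the two-group case t² equals F exactly. Significance level 0.05,
configurable.

## The synthetic generator

The clinical corpus (170 native-Chinese subjects, 85 depressed / 85
control, 29 recordings each, 4930 recordings) is available only on
request, so the package generates datasets with the structural and
statistical properties the method actually relies on:

* the subject/recording hierarchy with the corpus' gender × label cell
  counts (34/51 control M/F, 32/53 depressed M/F) and 29 recordings per
  subject;
* a scalar subject random effect b_s ~ N(0, σ_b²), σ_b = 0.5 — recordings
  of one subject are correlated, which is exactly why speaker-independent
  folds and subject-level fusion matter;
* a per-category low-rank latent structure: each category block is a
  fixed random linear image of an m = 5 dimensional latent vector plus
  independent feature noise (σ_e = 1). The class signal enters the
  *latent* mean (size δ_c along a fixed direction), not the raw feature
  means, so the reduction step is on the critical path of any successful
  classification;
* effect sizes δ = 0.3 / 0.5 / 0.5 / 0.1 for MFCC / PROS / SPEC / GLOT.
  No quantitative effect sizes are published for the clinical features;
  these defaults are chosen once to reproduce the *qualitative* findings —
  glottal features clearly weakest, prosodic/spectral strongest, MFCC in
  between — at realistic per-recording accuracies (high 50s to 60s
  percent), and the subject-effect direction is orthogonal to the class
  direction so the two are identifiable.

The generator does **not** emulate acoustic realism (no waveform level),
task/emotion differences among the 29 recordings, gender-specific effect
sizes (cell counts only, by default), or heavy-tailed feature
distributions. Passing tests on synthetic data therefore demonstrate that
the pipeline is implemented correctly and behaves as the method predicts
under its own assumptions — not that any particular accuracy would be
attained on clinical recordings.

`recoverEffects()` inverts the known loading matrices to re-estimate the
δ_c from a generated dataset; the acceptance suite checks recovery within
±0.1 at the full corpus size.

## Problem sizes used by the simulation suites

The statistical property suites run on scaled-down studies chosen once:
a quarter-scale schema (category widths 158/238/94/8, preserving the real
630/952/378/32 proportions), 8 subjects per gender × label cell with 29
recordings each, and 3-fold speaker-independent cross-validation, repeated
over 10 seeds for the ordering claims (subject-level ≥ recording-level
accuracy; ensemble ≥ median single-subspace classifier; glottal-only below
prosodic-only and spectral-only), each asserted by a one-sided sign test
at p < 0.05 rather than per-seed. Null calibrations (all δ = 0, σ_b = 0)
use 20 subjects with ten folds and expect chance-level accuracy within a
binomial band; the ANOVA+LSD type-I rate is checked on 1000 null
replicates. The full-width 1992-feature schema is exercised where it is
cheap: generation, composition summaries, effect recovery and schema/IO
round trips.

## Design decisions that were genuinely open

* **Column order** of the full feature vector is the schema's category
  order (MFCC, PROS, SPEC, GLOT), making every subspace a concatenation
  of contiguous blocks. The source tables never state a column order;
  all other modules depend only on the schema object, and 1-based
  indexing is used throughout, as everywhere in R.
* **Subject fusion rule.** The subject-level algorithm is described only
  as using all 29 recordings' classification results; summing the
  probability masses (equivalently, thresholding the mean normalized
  probability) is this package's reconstruction, chosen because it uses
  the base classifiers' uncertainty rather than discarding it at the
  recording threshold. Majority voting is available behind the `fusion`
  switch for comparison.
* **Per-fold refitting.** Whether reduction was refit per
  cross-validation fold is unstated in the source; refitting everything
  per fold is the only choice that keeps the evaluation free of test-set
  information, and `checkLeakage()` verifies it mechanically on every
  report.
* **Stratification** of folds by label (not by gender or any finer cell)
  prevents degenerate single-class folds at realistic per-gender subject
  counts.
* **Serialization** uses R's native RDS format for models and truth
  objects; determinism is guaranteed at the object level (identical data,
  configuration and seed give bit-identical serialized models, asserted
  in the tests).

## Known limitations

* LLE cost grows as O(n²p + n³) per subspace with training-set size n;
  the dense eigendecomposition is the bottleneck above a few thousand
  recordings per stratum.
* The out-of-sample extension degrades for test points far from the
  training manifold (their neighbour weights extrapolate).
* Subjects with fewer than 29 recordings are fused over whatever is
  present; no imputation or reweighting.
* Single-subspace probabilities are calibrated only through the logistic
  link; no post-hoc calibration is applied before summing.
* The ANOVA/LSD machinery assumes approximately normal, equal-variance
  fold metrics — adequate for ten-fold accuracy comparisons, but the
  package does not test those assumptions for you.
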