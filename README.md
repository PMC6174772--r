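# elrdd

Speaker-independent detection of depression from acoustic speech features,
by an ensemble of logistic regressions over category-combination feature
subspaces (ELRDD), with subject-level decision fusion over a subject's
recordings (ELRDD-E).

## The problem and the model

Clinically depressed speech differs acoustically from healthy speech, and a
per-recording feature vector — mel-frequency cepstral coefficients (MFCC),
prosodic (PROS), spectral (SPEC) and glottal (GLOT) descriptors with their
statistical functionals, 1992 features in total — carries a weak but real
class signal. Because the four categories are extracted by very different
methods, they are complementary, and every non-empty combination of them is
a usable feature subspace: with 4 categories there are K = 2⁴ − 1 = 15
subspaces (MFCC; PROS; …; MFCC+PROS+SPEC+GLOT).

For each subspace k, the pipeline standardizes the subspace columns,
reduces them by locally linear embedding (LLE, with a deterministic
neighbour-weight out-of-sample extension for test recordings), and fits a
logistic regression with weights w⁽ᵏ⁾ by (ridge-penalized) maximum
likelihood on the embedded training coordinates, with label y = 1 for
depressed and y = 0 for control recordings. A recording x with subspace
representations x⁽ᵏ⁾ is scored by summing the per-subspace class
probabilities:

    s1(x) = Σₖ σ(w⁽ᵏ⁾·x⁽ᵏ⁾),      s0(x) = Σₖ [1 − σ(w⁽ᵏ⁾·x⁽ᵏ⁾)],

so s1 + s0 = K, and the recording is called depressed when s1/K ≥ τ
(default τ = 0.5, ties positive). A subject with recordings r = 1…R
(29 per subject in the reference corpus) is called depressed when
S1 = Σᵣ s1(r) ≥ S0 = Σᵣ s0(r) — probability-mass fusion over all of the
subject's recordings.

Evaluation is speaker-independent ten-fold cross-validation (folds
partition subjects, stratified by label; every pipeline stage is refit per
fold), reporting sensitivity, specificity and accuracy with depressed as
the positive class, and one-way ANOVA with Fisher LSD post-hoc tests for
comparing classifier or feature-set results across folds.

The clinical corpus this method was designed for is not redistributable,
so the package includes a synthetic generator that emulates its structure:
85 controls (34 M / 51 F) and 85 depressed subjects (32 M / 53 F), 29
recordings per subject, subject random effects, and a low-rank latent
class signal per category with the glottal block weakest
(δ = 0.3 / 0.5 / 0.5 / 0.1 for MFCC / PROS / SPEC / GLOT).

## Worked example

```r
library(elrdd)

schema <- defaultSchema()
schema
#> FeatureSchema: 1992 features, 4 categories, 16 subcategories
#>   MFCC=630, PROS=952, SPEC=378, GLOT=32

subs <- enumerateSubspaces(schema)
subs[[8]]
#> Subspace 8: PROS + SPEC (1330 columns)

# a scaled-down synthetic study: quarter-scale schema (category widths
# proportional to the full one), 8 subjects per gender x label cell
quarter <- FeatureSchema(data.frame(
  category    = c("MFCC", "PROS", "PROS", "PROS", "SPEC", "SPEC", "GLOT"),
  subcategory = c("m1", "p1", "p2", "p3", "s1", "s2", "g1"),
  count       = c(158L, 120L, 80L, 38L, 52L, 42L, 8L)))
gd <- generateDataset(syntheticConfig(
  counts = c(maleControl = 8L, femaleControl = 8L,
             maleDepressed = 8L, femaleDepressed = 8L),
  recordingsPerSubject = 29L, schema = quarter, seed = 1L))
gd$dataset
#> SpeechFeatureSet: 928 recordings x 498 features, 32 subjects
#>   labels: 464 depressed / 464 control recordings

cv <- crossValidate(gd$dataset, elrddConfig(knn = 10, dim = 6, lambda = 1),
                    nFolds = 3, seed = 1)
cv
#> Speaker-independent cross-validation, 3 folds
#>   recording level: sens 58.84% / spec 58.62% / acc 58.73%
#>   subject level:   sens 87.50% / spec 87.50% / acc 87.50%
```

The per-recording ensemble is modestly better than chance on this noisy,
subject-clustered task; fusing the 29 recordings of each subject averages
the recording noise away and lifts subject-level accuracy well above the
recording-level one — the pattern the method is built around. Real
per-recording feature tables can be read with `readFeatureTable()` (CSV
with `subject_id, gender, label, task_id` plus one column per feature) and
used identically; `inst/scripts/elrdd` wraps the same functions as a
command line (`simulate`, `train`, `score`, `classify-subjects`,
`evaluate`).

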