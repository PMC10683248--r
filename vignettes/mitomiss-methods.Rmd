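---
title: "Methods: panel annotation and pathogenicity scoring for mitochondrial missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel annotation and pathogenicity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomiss)
```

## Scope and model

`mitomiss` addresses variant triage for primary mitochondrial disease: it
restricts VCF variants to a mitochondrial gene panel, attaches a typed
annotation schema, and scores missense variants with a disease-specific
classifier. The scorer is penalised logistic regression on preprocessed
features,

$$\Pr(\text{pathogenic} \mid x) = \sigma\!\left(b + \textstyle\sum_i \omega_i x_i\right),$$

fitted by IRLS (Newton) on the binomial likelihood with an L2 penalty on
the slopes (intercept unpenalised). Logistic regression is the shipped
family because its probabilities are directly interpretable against
clinical-guideline thresholds and its coefficients give transparent
feature importances $|\omega_i|$; five alternative families (AdaBoost over
decision stumps, decision tree, random forest, k-nearest neighbours, SVM)
are available and compared by nested cross-validation.

## The gene registry and annotation engine

The panel is a *gene registry*: one record per gene with a 1-based,
inclusive genomic interval, strand, a category from
{mt_protein_coding, disease_nuclear, mito_localized_nuclear}, the known
transcripts and the MANE representative among them. The panel used in the
motivating application covers 1461 genes (13 mitochondrial protein-coding,
321 nuclear disease genes, 1127 mitochondrially localised nuclear genes)
and 6942 transcripts; the registry here is data, not code, so any panel
with those columns loads. Published descriptions of this panel elsewhere
quote a slightly different count of "1448" targets; we treat the tabulated
per-category registry totals (1461/6942) as authoritative and simply
report what is loaded.

Annotation fields are typed (integer, boolean, continuous), levelled
(variant, gene, transcript) and categorised into six groups, of which
`mito_specific` is the group whose removal defines the reduced feature
set. The full 349-field production schema is configuration; tests and
examples use small synthetic schemas plus a 115-field panel shape whose
`mito_specific` block has 30 fields, so the full/reduced split is
115 → 85 columns.

Engine conventions, chosen once and covered by tests:

* Coordinates are 1-based and inclusive at both interval ends (VCF
  convention); filtering is verified against a brute-force interval scan.
* Multi-allelic records are decomposed into one key per ALT before
  filtering, since scoring is per-allele.
* A variant inside two overlapping panel genes is emitted once per gene —
  transcript-level annotations differ per gene.
* Missense status is taken from a consequence term (an INFO key or a
  variant-level source column); codon translation is out of scope, as the
  annotation engine sits downstream of a consequence caller.
* When a gene's MANE transcript is absent from the transcripts observed in
  the sources, the fallback is the lexicographically smallest observed id:
  deterministic and auditable.
* Missing values are rendered `"."` in all tabular output; values that
  fail dtype coercion are recorded as missing and counted in a
  coercion-failure report rather than aborting a run.

## Feature pipeline

Missing feature values are imputed by k-nearest neighbours (default
k = 5, configurable): the distance between rows is the Euclidean distance
over mutually observed features, rescaled by
$\sqrt{p_\text{total}/p_\text{observed}}$ — the standard incomplete-data
convention — and each missing cell is the unweighted mean of that feature
over the k nearest rows where it is observed. Distance ties at the k-th
neighbour enlarge the averaging set, which removes row-order dependence.
Neighbour search uses the training matrix only; transforming new rows
searches the completed training reference.

Normalisation is min–max to [0, 1] per feature, fitted on training data;
constant features get scale 1 (mapping to 0) and are flagged. Min–max was
chosen over z-scoring because most panel features (predictor scores,
allele frequencies, boolean flags) are naturally bounded. Imputation runs
before normalisation: neighbour distances are computed on the features'
native scales, and fixing the order makes the fitted state reproducible.
Both choices were genuinely open design decisions; they are documented
here, asserted by tests, and the normaliser is swappable in code.

All preprocessing state is fit/transform split, so cross-validation can
(and does) refit it inside every fold — a sentinel-feature test plants
extreme values in held-out rows and asserts the fitted parameters equal
the training-fold extrema exactly.

## Model selection and training

Nested cross-validation compares the six families: an inner stratified
loop (default fivefold) grid-searches each family's hyperparameters on
every outer-training fold, the tuned model is refitted on the fold and
scored on the outer held-out fold (default tenfold). Reports carry
per-fold accuracies with mean ± sd, and pooled outer-fold
accuracy/precision/AUC/F1/recall/MCC per family. Folds are stratified
with a fixed logged seed; training sets in this application are balanced
1:1 benign:pathogenic, so stratification is near-neutral but protects
against degenerate folds. The default logistic penalty is L2
(λ = 1e-3 by default, tuned over a log grid in CV) for coefficient
stability; IRLS runs to a step tolerance of 1e-6 with a 1000-iteration
cap. No AdaBoost implementation ships in our dependency set, so the
classic two-class discrete AdaBoost over `rpart` stumps is implemented
in-package, with the boosted margin mapped to a probability through
$\sigma(2F)$.

`fit_scorer()` fits preprocessing on the entire provided training matrix
and then the classifier; the returned `variant_scorer` object carries
coefficients, preprocessing state and the default 0.5 threshold, and has
`predict`, `coef` (normalised or raw scale), `print`, `summary` and
`plot` methods plus JSON persistence. The raw-scale coefficient map
$\omega_i^{\text{raw}} = \omega_i/(\max_i - \min_i)$ is what makes
parameter-recovery tests against a generative model on raw features
meaningful.

## Evaluation suite

Binary classification uses the strict rule "pathogenic iff score > t", so
the 0.5 default, the ROC sweep and the stratification bounds
(Pr > 0.75 pathogenic, Pr < 0.15 benign, VUS between) share one
convention; a score exactly at a cutoff is never called pathogenic. The
twelve-metric panel is the missing-score count plus
precision/NPV/specificity/FPR/recall/FNR/accuracy (percentages),
MCC, AUC, F1 and average precision. Undefined ratios (e.g. precision with
no predicted positives) are explicit `NA` markers, never silent zeros.
Rows without a score are excluded from all metrics and reported in
`missing`, matching how tools with partial coverage are compared.

ROC sweeps group tied scores into single steps; AUC is the trapezoidal
area and is tested to equal the tie-corrected normalised Mann–Whitney
statistic to 1e-12. Average precision is the step-wise
$\sum_k (R_k - R_{k-1}) P_k$. The "optimal" threshold maximises Youden's
J = TPR − FPR (ties resolved to the smallest finite threshold); Youden is
an assumption — recommended thresholds reported alongside published
models do not name their method — and is therefore computed from data,
never hard-coded.

## Simulated-exome benchmark

The benchmark emulates Mendelian-exome triage: background exomes of about
400 variants (after removing common variants at MAF > 1%; unknown
frequency is treated as rare and kept), one spiked causative variant per
exome, then per tool the percent of scored variants above the tool's
recommended threshold (candidate-list size) and the causative variant's
rank. Ranking ties are pessimistic — the causative variant is placed
after all equal-scoring background variants — so reported ranks are
conservative. Rank lists are summarised as mean ± sample sd and median,
and compared between tools with a Mann–Whitney test: exact by exhaustive
enumeration of group assignments when $n_a n_b \le 200$ (correct under
ties), otherwise the tie-corrected normal approximation. Cohort-size
defaults of 29 and 170 exomes echo the two cohorts used in the motivating
application.

## Synthetic fixtures

Every input the suite needs is generated in code from mandatory seeds:

* registries with non-overlapping intervals per contig and 1–5 transcripts
  per gene (optionally exact per-category transcript totals, to reproduce
  a published panel shape);
* VCFs with a controlled fraction of in-panel positions;
* per-level annotation source tables with completely-at-random missing
  tokens;
* labelled feature matrices drawn from a known logistic model — features
  N(0,1)/Bernoulli(0.5)/uniform-integer by dtype, labels
  Bernoulli(σ(b + ω·x)), MCAR missingness at a stated rate;
* background exomes with Poisson-jittered sizes, mostly-rare MAFs and
  benign-like Beta(2, 8) tool scores.

Because the label generator matches the scorer's assumed model exactly,
parameter recovery is a valid end-to-end test: at n = 5000 with
ω = (2, −1, 0) the fitted raw-scale coefficients come back within ±0.15
(the recovery harness uses zero missingness, so the generative and fitted
models coincide exactly). What synthetic fixtures deliberately do not
emulate: real inter-feature correlations, coverage-driven (non-random)
missingness, allele-frequency spectra or ClinVar label structure. Passing
tests therefore demonstrate algorithmic correctness, not clinical
performance; published evaluation numbers on curated clinical variant
sets (algorithm-comparison tables, curve thresholds, exome-cohort ranks)
are not reproducible from synthetic data and are not asserted anywhere.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at deliberately
modest sizes chosen to exercise the code paths: nested CV at 3–5 outer ×
3 inner folds on 200–300 rows, recovery at n ∈ {500, 5000}, imputation
oracles on matrices up to 10×5, rank-sum exactness up to group sizes of
8, and 29-exome benchmarks of ~400 variants. IRLS tolerance is 1e-6;
dual-implementation oracles (brute-force interval scan, exhaustive KNN
search, pair-counting AUC, permutation rank-sum, `glm`/`wilcox.test`
cross-checks) are kept independent of the implementation paths they
verify.

## Known limitations

* No consequence calling, liftover or mtDNA haplogroup handling; the
  engine trusts upstream consequence annotation.
* Persistence covers the logistic scorer only; tree/ensemble candidates
  are for comparison, not deployment.
* The exact-enumeration rank-sum test is limited to small groups by
  design (combinatorial growth); larger groups use the normal
  approximation without continuity correction.
* Probabilities are not recalibrated (no Platt/isotonic step); the
  stratification cutoffs assume reasonably calibrated scores.
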