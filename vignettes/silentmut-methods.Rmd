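---
title: "Methods: measuring the predictive power of silent mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the predictive power of silent mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the modelling strategy

Tumor-genomics pipelines usually restrict attention to non-silent mutations —
exonic variants that change the protein sequence. Silent variants
(synonymous coding changes, intronic, UTR and flanking-region mutations) can
nonetheless alter gene expression through transcription, splicing, mRNA
stability and translation, and may carry predictive signal for both diagnosis
and prognosis. `silentmut` treats this as a feature-class comparison problem:
build the same kinds of features from each mutation category, train the same
models under the same protocol, and compare performance per category, against
a combined dataset, and against null models that ignore the features
entirely.

Every analysis in the package works on two inputs: a MAF-style table of
somatic mutation calls (1-based inclusive coordinates, the TCGA classification
vocabulary, one row per patient-mutation) and a clinical table (cancer type,
vital status, days to death / last follow-up). A mutation is trusted as given:
the package performs no variant calling, liftover or re-annotation.

## Category sorting

Each record maps to exactly one of five categories via a configurable table
(`default_category_map()`): nine protein-altering classifications make
`NON_SILENT`; `Silent` makes `SYNONYMOUS`; `Intron` and `Splice_Region` make
`INTRON`; the UTR and flank classifications make `UTR` and `FLANK`.
Two decisions deserve note:

* `Splice_Site` (a coding-region annotation) is non-silent, whereas
  `Splice_Region` (annotated inside the intron) counts as intronic. This
  follows the convention that splice-site calls disrupt the protein product
  while splice-region variants are intronic sequence.
* Classifications the five buckets never claim (`RNA`, `IGR`,
  `Targeted_Region`, ...) are excluded and counted rather than forced into a
  category.

Patient identity is the first 12 characters of a TCGA-style barcode when
barcodes are present; a custom regular expression can be supplied otherwise.
Patients missing from either table, without a recorded cancer type, or with
multiple genomic samples are dropped by `filter_patients()`, which reports
per-reason counts.

## Feature engineering

For each category three resolutions are built over a fixed patient axis:

* **Low**: the number of the patient's category mutations per gene — one
  feature per gene with at least one such mutation in the cohort.
* **Medium**: the gene body (5'UTR through 3'UTR) is tiled into consecutive
  50-nucleotide segments anchored at the body's lowest genomic coordinate,
  and a mutation is assigned to the segment containing its start coordinate.
  The flank category instead gets exactly two per-gene features (5' and 3'
  side). Segments tile the genomic span, not a spliced transcript: the MAF
  alone determines the assignment, which keeps the construction reproducible
  without transcript models. Multi-nucleotide variants count once, in the
  segment of their start coordinate. Mutations outside the annotated body are
  clamped to the nearest terminal segment with a warning.
* **High**: one binary feature per exact mutation; the identifier
  `start-end-chrom-classification-type-ref-a1-a2` distinguishes different
  substitutions at the same position. Features carried by a single patient
  cohort-wide are discarded (the threshold is cohort-wide, not per cancer
  type, and is exposed as `min_carriers`).

The invariant that medium counts sum to the low count per (patient, gene,
category) is enforced by construction and by test. The five single-category
datasets plus their concatenation (the all-features dataset) are the six
analysis datasets. Matrices are stored sparse (`Matrix::dgCMatrix`) with a
feature-metadata sidecar; `binarize()` produces the 0/1 variants used by the
similarity analyses (high-resolution features are already binary and do not
change).

## Classification protocol

One-vs-all: for each included cancer type (strictly more than 200 patients by
default; configurable) the type's patients are positive and all other
included patients pooled negative. Per (type, dataset) a gradient-boosted
tree ensemble is fit on each of 10 stratified 0.7/0.3 splits and evaluated on
the held-out patients; metrics (accuracy, precision, recall, F1 with the 0
convention when P + R = 0) and gain-based feature importances are averaged
over the repeats. Design choices:

* **Learner.** Gradient-boosted decision trees (`xgboost`), with a small
  frozen hyperparameter set (`ova_params()`: 40 rounds, depth 6, eta 0.3,
  single thread for determinism). The protocol compares feature classes, not
  tuners, so no search is performed and class imbalance is left unweighted.
* **Pairing.** Split `r` always uses seed `base + r`, so every model sharing
  a repeat index sees the same patient partition and dataset comparisons are
  paired.
* **Importance.** Gain importance averaged across repeats, ties broken by
  feature id, chosen over split counts for stability.
* **Null model.** For each repeat the null predicts positive with probability
  equal to the training-set positive fraction, independently per test
  patient. Its expected precision and recall both equal the positive
  prevalence p, so its expected F1 is p — a property the tests check by
  Monte Carlo.

The **resolution ablation** retrains each task on high-only, high+medium and
all-resolution subsets under identical splits. The **balanced protocol**
controls for feature-count imbalance: using high-resolution features only,
patients are split into two equal halves; a model on the first half ranks
each category's features and the top K are kept (K defaults to the size of
the smallest category's feature set, so all six balanced datasets — five
categories plus their 5K-column concatenation — have equal width per
category); models are then retrained on the second half under the repeated
splits. When a selection model leaves fewer than K features with positive
importance, the selection is padded with the remaining features in id order
so the width contract holds exactly.

## Gene rankings and their analyses

Features with zero importance are discarded; the remainder map to genes in
importance order and only each gene's best rank is kept (rank 0 = most
important). On top of this the package computes: the category composition and
enrichment of top-k features (relative to the dataset composition); the
SNP/DEL/INS enrichment among top-k high-resolution features (low/medium
features carry no polymorphism type and are excluded from both numerator and
denominator); pairwise Spearman correlations of gene rankings between
single-category models (genes outside the intersection discarded, pairs with
fewer than 3 shared genes skipped, results averaged across cancer types; the
all-features model is excluded); the gene-by-category membership matrix of
top-10 gene lists; and the Spearman correlation between per-gene mutation
totals and gene rank (ranks reversed so "more mutated, more important" is a
positive rho). Top-10 gene lists may hold fewer than 10 genes when several
top features share a gene; no padding is applied and the length is recorded.
Because averaging p-values across cancer types has no canonical form, the
cross-model analysis reports both the mean p and a Fisher-combined p.

Ranked gene lists export as one-symbol-per-line text files, the input format
of common GO-enrichment tools; enrichment itself is out of scope.

## Cohort similarity and burden statistics

Jaccard similarity between two cancer types averages the per-patient-pair
score |F_a ∩ F_b| / |F_a ∪ F_b| over all cross-cohort pairs of 100 sampled
patients per type, repeated 5 times (samples drawn without replacement,
repetition r seeded as base + r). Two empty profiles score 0, defining away
the 0/0 case. All features are binarized first; raw-count Jaccard is
unsupported because the set-based definition only applies to binary profiles.
The misclassification rate between two types samples 250 patients per type,
splits 0.7/0.3 stratified, fits the same boosted-tree learner as the
classification branch (internal consistency), and computes
M = (|AB| + |BA|) / total on the held-out patients, averaged over 10
repetitions; the stored per-repetition confusion counts always sum to the
test-set size. Cohorts smaller than the sample size lower it with a message.

`f1_improvement()` and `mb_increase()` implement the percent-improvement and
percent-burden-increase statistics (patients with zero non-silent burden are
excluded and counted); both are exactly 0 when adding features changes
nothing, fixing the sign conventions. Their association across cancer types
is a Pearson correlation with r² reported.

## Survival estimation

All cancer types pool into a single cohort; the model never sees the cancer
type. Deceased patients contribute an event at `days_to_death`, alive
patients a censoring time at `days_to_last_followup`; patients with no
post-diagnosis information are excluded, as are deaths earlier than 20 days
after diagnosis ("less than": a death at exactly day 20 is kept). The
feature subset is all low-resolution features plus the 5,000 most prevalent
high-resolution features (ties at the cutoff broken by feature id); medium
resolution is excluded.

The forest is a random survival forest — 60 trees, maximal depth 32,
log-rank splitting on Kaplan-Meier estimates — backed by `ranger`; the
package owns the labels, exclusions, feature selection, the five stratified
0.7/0.3 repetitions (stratified by event status, since the event rate, not
the outcome time, is what a degenerate split would lose), per-patient curve
averaging across the repetitions in which a patient was held out, and
evaluation. Survival probabilities are read off the forest's step functions
at 100, 500, ..., 4500 days; the grid stops at 4500 days where follow-up
data become scarce.

The evaluation metric is the cumulative/dynamic time-dependent AUC: at time
t, risk is 1 − S_i(t); cases are patients with an event by t, controls are
patients still at risk beyond t, censored-before-t patients are omitted from
both sets, and ties count one half. No inverse-probability-of-censoring
weights are applied in the default estimator — the comparison of interest is
between feature sets under identical censoring, where the unweighted
estimator is adequate and exactly matches a brute-force pair enumeration
(which the tests exploit). The null model draws risk scores independently of
all covariates, giving a flat expected AUC of 0.5 at every time point; a
Kaplan-Meier-constant predictor is equivalent under the tie rule. Feature
importance is `ranger`'s permutation importance (out-of-bag concordance
degradation), averaged over repetitions, and feeds the gene-ranking
machinery unchanged.

## The synthetic cohort generator

The generator is first-class, tested code and defines the conditions under
which the package validates itself:

* **Annotation.** Each gene sits on its own chromosome (no overlap
  bookkeeping), laid out as 5' flank, 5'UTR, alternating exons and introns,
  3'UTR, 3' flank; exons split into a protein-altering part and a synonymous
  part so that every genomic position implies exactly one category. Gene
  bodies are at least 150 nt, keeping 50-nt segmentation non-degenerate.
* **Background.** Per patient and category, Poisson-many mutations land at
  length-weighted uniform positions in regions of that category. Background
  is drawn per category rather than per position, keeping cohorts desk-scale
  while preserving the strong category imbalance of real tumor data; the
  default rates (non-silent 10 ≫ intron 5 > UTR 3 > synonymous 2 > flank 1
  per patient) encode that ordering. The polymorphism mixture defaults to
  90% SNP / 7% DEL / 3% INS; synonymous events are always substitutions.
* **Signatures.** A planted signal is either an exact recurrent mutation
  (recoverable by a high-resolution feature) or a gene-level burden
  (recoverable by a low-resolution feature), carried independently with a
  configurable prevalence; the returned truth table and signal ids drive the
  recovery tests. Because the three resolutions deliberately alias the same
  planted mutation (exact id, its segment, its gene), tree models may credit
  any of the aliases; recovery checks therefore accept a signal at any of
  its resolutions.
* **Survival.** Event times are exponential proportional hazards,
  T ~ Exp(h0 · exp(Σ βj xij)), administratively censored at a horizon. The
  exponential baseline gives closed-form checks (the β = 0 cohort must track
  the known survival curve); other baselines can be layered by replacing the
  single `rexp()` draw.

What the generator does **not** emulate: sequence context (no trinucleotide
signatures), exome-capture bias, per-gene mutation-rate heterogeneity beyond
region length, clonal structure, and non-administrative censoring. Passing
recovery tests therefore demonstrate that the pipeline's machinery is
correct and sensitive to planted signal at realistic sizes — not that any
particular biological claim holds on real cohorts.

## Numerical choices and degenerate inputs

* All randomized routines take explicit seeds; repetition r derives its seed
  as base + r, and a single master seed drives `run_all()`. RNG state is
  restored after every simulation call.
* Stratified splits guarantee both classes in both halves whenever a class
  has two members; a split that still degenerates is resampled with an
  incremented seed and logged.
* Ties: importance ties break by feature id; prevalence ties at the survival
  feature cutoff break by feature id; AUC ties count one half.
* Degenerate statistics are reported missing rather than guessed: Spearman
  rho on constant input, misclassification pairs with undersized cohorts
  (sample size lowered, logged), polymorphism enrichment with no
  high-resolution features in the top k, burden increase when every patient
  has zero non-silent burden, AUC at times with no comparable pairs.
* A booster that never splits (for example a single near-constant feature)
  yields an empty importance table rather than an error; zero-feature
  datasets are rejected with a clear message.

## Problem sizes

The validation suite and the acceptance script run the protocols at sizes a
single CPU handles in minutes, chosen as the smallest cohorts at which the
planted effects are comfortably detectable: three 150-patient types
(prevalence 0.4, background 2 mutations per category) for classification
recovery; four 100-patient types with signature-gene overlaps spanning 0 to
0.9 (Jaccard samples of 40, misclassification samples of 100) for the
similarity-misclassification correlation; and a 600-patient cohort with a
hazard ratio of 3 on a 30%-prevalence mutation and roughly 40% administrative
censoring for survival recovery. Protocol constants that mirror the study
design (10 splits, 5/10 similarity repetitions, the 200-patient cohort
threshold, 60-tree depth-32 forests, the 100-4500-day grid) are defaults
throughout and scale up unchanged.

## Known limitations

* Gradient-boosting hyperparameters are frozen, not tuned; absolute F1
  values on real data would change with tuning even though the
  feature-class comparisons are designed to be robust to it.
* Genomic-span segmentation differs from transcript-coordinate segmentation
  for genes with long introns; segment features are comparable within a
  dataset but not across annotation versions.
* The unweighted AUC estimator is biased under heavy, covariate-dependent
  censoring; an IPCW variant would be the remedy if per-category censoring
  patterns differed, which the administrative-censoring simulations avoid.
* Survival is estimated on the pooled cohort; per-cancer-type survival
  models need substantially more data per type and are out of scope.
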