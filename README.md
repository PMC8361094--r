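# silentmut

Quantifying the predictive power of **silent somatic mutations** — synonymous,
intronic, UTR and flanking-region variants — for cancer-type classification
and survival estimation, in comparison with the non-silent mutations that
dominate most tumor-genomics analyses.

Most predictive models built from tumor sequencing discard every variant that
does not change an amino acid. Yet silent mutations can perturb transcription,
splicing, mRNA stability and translation, and may therefore carry diagnostic
and prognostic signal of their own. `silentmut` provides a tested pipeline for
measuring that signal: it sorts MAF-style mutation calls into five categories,
engineers patient-by-feature matrices at three genomic resolutions, trains
one-vs-all classifiers per cancer type against label-distribution null
models, derives gene importance rankings and their cross-model correlations,
relates pairwise cohort similarity to misclassification, and fits random
survival forests evaluated with time-dependent AUC. A synthetic-cohort
generator with planted mutation signatures and proportional-hazards survival
times supplies full ground truth, so every claim the pipeline makes can be
verified by recovery experiments.

The package is aimed at statistical genomics researchers who want to evaluate
feature classes (rather than ship a diagnostic model), and at methodologists
who need a self-validating reference implementation of the protocol.

## The statistics at the core

**Mutation categories.** Each retained MAF record maps to exactly one of
`NON_SILENT` (missense, nonsense, nonstop, frameshift/in-frame indels,
translation start site, splice site), `SYNONYMOUS` (`Silent` in the MAF
dialect), `INTRON` (incl. `Splice_Region`), `UTR`, or `FLANK`.

**Three feature resolutions** per category: low = mutation count per whole
gene; medium = count per 50-nucleotide gene segment (plus one feature per
flank side); high = binary indicator of an exact mutation
(`start-end-chrom-classification-type-ref-allele1-allele2`), with mutations
seen in a single patient discarded.

**Classification.** For each (cancer type, dataset) pair a gradient-boosted
tree ensemble is trained on 10 stratified 0.7/0.3 splits and scored with

    F1 = 2 * P * R / (P + R)

against a null model that guesses labels from the training-set label
distribution. Improvement from adding silent features and the accompanying
mutational-burden increase are

    F1_improvement = (F1_all - F1_non_silent) / F1_non_silent * 100
    MB_increase    = mean_i [ (MB_i,all - MB_i,non_silent) / MB_i,non_silent * 100 ]

**Cohort similarity.** For a pair of cancer types A, B the Jaccard score
averages |F_a ∩ F_b| / |F_a ∪ F_b| over all sampled cross-cohort patient
pairs (binary profiles; 100 patients per type, 5 repetitions), and the
misclassification rate is M = (|AB| + |BA|) / (|AA| + |AB| + |BA| + |BB|)
from a two-class model on 250 sampled patients per type, 10 repetitions;
their association is summarized by Spearman's rho across pairs.

**Survival.** Patients with a death under 20 days after diagnosis or no
post-diagnosis follow-up are excluded; a random survival forest (60 trees,
depth 32, log-rank splitting; all low-resolution plus the 5,000 most
prevalent high-resolution features) is fit on 5 stratified 0.7/0.3 splits,
and held-out survival curves are scored by the cumulative/dynamic AUC at
100–4500 days against a covariate-free null whose expected AUC is 0.5.

## Worked example

Simulate two 150-patient cohorts with planted signatures — an exact
non-silent substitution in `GENE001` for "LUAD" and a gene-level intronic
burden in `GENE002` for "BRCA", each carried by 40% of that type's patients —
then ask whether the all-features model distinguishes LUAD from the rest
better than guessing:

```r
library(silentmut)

ann <- make_annotation(n_genes = 6, seed = 1)
signals <- list(
  signature_signal("LUAD", "GENE001", "NON_SILENT", prevalence = 0.4, kind = "mutation"),
  signature_signal("BRCA", "GENE002", "INTRON",     prevalence = 0.4, kind = "gene")
)
sim <- simulate_cohort(ann, signals, cohort_config(c(LUAD = 150, BRCA = 150), seed = 1))
patients <- sort(unique(sim$clinical$patient_id))
datasets <- build_datasets(sim$mutations, ann, patients)
datasets$ALL
#> <feature_matrix> 300 patients x 483 features
#>              HIGH LOW MEDIUM
#>   FLANK         0   6     12
#>   INTRON        9   6    141
#>   NON_SILENT  124   6     60
#>   SYNONYMOUS   16   6     34
#>   UTR          17   6     40

labels <- make_ova_labels(sim$clinical, "LUAD", min_cohort = 100)
scheme <- split_scheme(n_repeats = 10, seed = 1)
fit <- train_ova(datasets$ALL, labels, scheme)
fit
#> <ova_result> 300 patients, 483 features, 10 repeats
#> mean F1 0.630 (precision 0.674, recall 0.596, accuracy 0.652)
null_model(labels[patients], scheme)
#> <null_result> mean F1 0.501 over 10 repeats
```

The classifier's mean F1 (0.630) clearly exceeds the null's (0.501): the
planted 40%-prevalence signature is detectable over a Poisson background of
about 21 mutations per patient. The importance ranking puts the planted
substitution first, and collapsing features to genes recovers `GENE001` at
rank 0:

```r
head(fit$importance, 3)
#>                                       feature_id importance
#> 1 551321-551321-chr1-Nonsense_Mutation-SNP-C-C-G 0.25568028
#> 2                        GENE006|NON_SILENT|gene 0.03186918
#> 3                            GENE003|INTRON|gene 0.02916010
head(derive_gene_ranking(fit$importance, feature_gene_map(datasets$ALL$features)), 3)
#>   gene_symbol rank
#> 1     GENE001    0
#> 2     GENE006    1
#> 3     GENE003    2
```

`run_all(run_config(...))` chains every stage — preprocessing, the
classification grid with nulls, rankings, pairwise similarity, burden
statistics and the survival branch — into one seeded, reproducible bundle of
TSV tables; `export_ranked_gene_lists()` writes one-symbol-per-line ranked
lists suitable for external GO-enrichment tools.

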