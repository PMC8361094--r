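# Pairwise cohort statistics: Jaccard similarity between patients' binary
# mutation profiles, two-class misclassification rates, the F1-improvement
# and mutational-burden-increase statistics, and their correlations.

#' Jaccard similarity of two binary feature sets
#'
#' `|A intersect B| / |A union B|`, where each set holds the ids of a
#' patient's features equal to 1. Two empty profiles have similarity 0 (the
#' 0/0 case is defined away).
#'
#' @param f_a,f_b Vectors of feature ids (or any atomic values) with value 1.
#' @return Numeric in `[0, 1]`.
#' @export
#' @examples
#' jaccard(c(1, 2, 3), c(2, 3, 4))  # 0.5
jaccard <- function(f_a, f_b) {
  f_a <- unique(f_a); f_b <- unique(f_b)
  u <- length(union(f_a, f_b))
  if (u == 0L) return(0)
  length(intersect(f_a, f_b)) / u
}

# mean pairwise Jaccard between two binary profile matrices (rows=patients)
.mean_pairwise_jaccard <- function(A, B) {
  inter <- as.matrix(A %*% Matrix::t(B))
  sizes_a <- Matrix::rowSums(A)
  sizes_b <- Matrix::rowSums(B)
  uni <- outer(sizes_a, sizes_b, "+") - inter
  j <- ifelse(uni > 0, inter / uni, 0)
  mean(j)
}

#' Average Jaccard similarity between two cancer-type cohorts
#'
#' Per repetition, `sample_size` patients are drawn without replacement from
#' each cohort and the Jaccard similarity is averaged over all
#' `sample_size * sample_size` cross-cohort patient pairs; the final score is
#' the mean over `n_reps` repetitions. Features are binarized first.
#'
#' @param features A `feature_matrix` over all patients.
#' @param clinical Clinical data frame.
#' @param type_a,type_b The two cancer types.
#' @param sample_size Patients drawn per cohort per repetition (default 100;
#'   lowered to the smaller cohort size with a message if necessary).
#' @param n_reps Number of repetitions (default 5).
#' @param seed Base seed; repetition `r` uses `seed + r`.
#' @return List with `J` (final score), `per_rep`, `sample_size`.
#' @export
jaccard_pair_protocol <- function(features, clinical, type_a, type_b,
                                  sample_size = 100L, n_reps = 5L,
                                  seed = 1L) {
  fm <- binarize(features)
  pats_a <- clinical$patient_id[clinical$cancer_type == type_a]
  pats_b <- clinical$patient_id[clinical$cancer_type == type_b]
  smallest <- min(length(pats_a), length(pats_b))
  if (smallest < sample_size) {
    message(sprintf("sample size lowered from %d to %d (smallest cohort)",
                    sample_size, smallest))
    sample_size <- smallest
  }
  per_rep <- vapply(seq_len(n_reps), function(r) {
    local_seed(seed + r, {
      a <- sample(pats_a, sample_size)
      b <- sample(pats_b, sample_size)
      .mean_pairwise_jaccard(fm$values[a, , drop = FALSE],
                             fm$values[b, , drop = FALSE])
    })
  }, numeric(1))
  list(J = mean(per_rep), per_rep = per_rep, sample_size = sample_size,
       type_a = type_a, type_b = type_b)
}

#' Pairwise misclassification rate between two cancer types
#'
#' Per repetition, `sample_size` patients are drawn from each type, split
#' stratified 0.7/0.3, a two-class boosted-tree model is fit on the training
#' patients, and the misclassification rate
#' `M = (|AB| + |BA|) / (|AA| + |BB| + |AB| + |BA|)` is computed on the test
#' patients, where `|AB|` counts group-A patients classified as group B. The
#' final rate is the mean over `n_reps` repetitions.
#'
#' @inheritParams jaccard_pair_protocol
#' @param sample_size Patients per type per repetition (default 250).
#' @param n_reps Repetitions (default 10).
#' @param test_fraction Held-out fraction per repetition.
#' @param params [ova_params()] hyperparameters for the two-class model.
#' @return List with `M` (final rate), `per_rep`, and `confusion` (one row
#'   per repetition: counts `AA`, `AB`, `BA`, `BB`).
#' @export
misclassification_protocol <- function(features, clinical, type_a, type_b,
                                       sample_size = 250L, n_reps = 10L,
                                       seed = 1L, test_fraction = 0.3,
                                       params = ova_params()) {
  X <- if (inherits(features, "feature_matrix")) features$values else features
  pats_a <- clinical$patient_id[clinical$cancer_type == type_a]
  pats_b <- clinical$patient_id[clinical$cancer_type == type_b]
  smallest <- min(length(pats_a), length(pats_b))
  if (smallest < sample_size) {
    message(sprintf("sample size lowered from %d to %d (smallest cohort)",
                    sample_size, smallest))
    sample_size <- smallest
  }
  confusion <- matrix(0L, n_reps, 4L,
                      dimnames = list(NULL, c("AA", "AB", "BA", "BB")))
  for (r in seq_len(n_reps)) {
    sel <- local_seed(seed + r, {
      list(a = sample(pats_a, sample_size), b = sample(pats_b, sample_size))
    })
    pats <- c(sel$a, sel$b)
    y <- c(rep(1L, sample_size), rep(0L, sample_size))  # 1 = type A
    sp <- .stratified_split(y, test_fraction, seed + r)
    bst <- .fit_gbt(X[pats[sp$train], , drop = FALSE], y[sp$train], params,
                    seed + r)
    pred <- as.integer(stats::predict(bst, xgboost::xgb.DMatrix(
      X[pats[sp$test], , drop = FALSE])) > 0.5)
    truth <- y[sp$test]
    confusion[r, ] <- c(sum(truth == 1 & pred == 1),  # AA
                        sum(truth == 1 & pred == 0),  # AB
                        sum(truth == 0 & pred == 1),  # BA
                        sum(truth == 0 & pred == 0))  # BB
  }
  per_rep <- (confusion[, "AB"] + confusion[, "BA"]) / rowSums(confusion)
  list(M = mean(per_rep), per_rep = per_rep, confusion = confusion,
       sample_size = sample_size, type_a = type_a, type_b = type_b)
}

#' Correlation between Jaccard similarity and misclassification rate
#'
#' Spearman correlation across all unordered cancer-type pairs between the
#' pairwise Jaccard similarity `J` and the pairwise misclassification rate
#' `M`.
#'
#' @param pairs Data frame with columns `J` and `M`, one row per pair (at
#'   least 3 pairs).
#' @return List with `rho`, `p` and `n_pairs` (`rho` is `NA` when either
#'   statistic is constant across pairs).
#' @export
similarity_vs_misclassification <- function(pairs) {
  if (nrow(pairs) < 3L) stopf("need at least 3 pairs, got %d", nrow(pairs))
  st <- spearman_stat(pairs$J, pairs$M)
  list(rho = st$rho, p = st$p, n_pairs = nrow(pairs))
}

#' Percent F1 improvement from adding silent features
#'
#' `(F1_all - F1_ns) / F1_ns * 100`: the signed percent improvement of the
#' all-features model over the non-silent model.
#'
#' @param f1_all F1 score of the all-features model.
#' @param f1_ns F1 score of the non-silent model (> 0; `NA` returned
#'   otherwise).
#' @return Signed percent.
#' @export
#' @examples
#' f1_improvement(0.5, 0.4)  # 25
f1_improvement <- function(f1_all, f1_ns) {
  ifelse(f1_ns > 0, (f1_all - f1_ns) / f1_ns * 100, NA_real_)
}

#' Percent mutational-burden increase from adding silent mutations
#'
#' The mean over patients of the per-patient percent increase in mutational
#' burden when silent mutations are added to non-silent mutations; patients
#' with zero non-silent burden are excluded and counted.
#'
#' @param burden_all Named numeric vector: per-patient mutation count in the
#'   all-features data.
#' @param burden_ns Named numeric vector: per-patient non-silent mutation
#'   count (same patients).
#' @return List with `mb_increase` (percent; `NA` when every patient is
#'   excluded) and `n_excluded`.
#' @export
#' @examples
#' mb_increase(c(p1 = 3, p2 = 5), c(p1 = 2, p2 = 2))  # (50 + 150) / 2 = 100
mb_increase <- function(burden_all, burden_ns) {
  if (!is.null(names(burden_ns))) burden_ns <- burden_ns[names(burden_all)]
  ok <- !is.na(burden_ns) & burden_ns > 0
  if (!any(ok)) return(list(mb_increase = NA_real_, n_excluded = length(burden_all)))
  pct <- (burden_all[ok] - burden_ns[ok]) / burden_ns[ok] * 100
  list(mb_increase = mean(pct), n_excluded = sum(!ok))
}

#' Per-patient mutational burden
#'
#' Number of retained mutations per patient, optionally restricted to a set
#' of categories.
#'
#' @param mutations Mutation data frame.
#' @param patients Patient axis (patients without mutations get 0).
#' @param categories Categories to count (default: all five).
#' @param category_map Classification-to-category table.
#' @return Named numeric vector of counts.
#' @export
mutational_burden <- function(mutations, patients,
                              categories = mutation_categories(),
                              category_map = default_category_map()) {
  mutations <- .categorized(mutations, category_map)
  mutations <- mutations[mutations$category %in% categories, , drop = FALSE]
  counts <- table(factor(mutations$patient_id, levels = patients))
  stats::setNames(as.numeric(counts), patients)
}

#' Correlation between F1 improvement and mutational-burden increase
#'
#' Pearson correlation across cancer types between the percent F1
#' improvement and the percent mutational-burden increase gained by adding
#' silent features, with `r^2` (the fraction of F1-change variance explained
#' by the burden change).
#'
#' @param records Data frame with columns `f1_improvement` and `mb_increase`,
#'   one row per cancer type (at least 3).
#' @return List with `r`, `r_squared`, `p` and `n`.
#' @export
improvement_burden_correlation <- function(records) {
  ok <- stats::complete.cases(records[c("f1_improvement", "mb_increase")])
  records <- records[ok, , drop = FALSE]
  if (nrow(records) < 3L) stopf("need at least 3 cancer types, got %d", nrow(records))
  ct <- stats::cor.test(records$f1_improvement, records$mb_increase,
                        method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p = ct$p.value, n = nrow(records))
}
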