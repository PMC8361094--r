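# One-vs-all cancer-type classification with gradient-boosted trees, the
# label-distribution null model, the resolution ablation and the balanced
# (equal-width) dataset protocol.

#' Repeated stratified split scheme
#'
#' @param n_repeats Number of random splits (default 10).
#' @param test_fraction Held-out fraction per split (default 0.3).
#' @param seed Base seed; split `r` uses `seed + r` so every model sharing a
#'   repeat index sees the same patient partition.
#' @return A `split_scheme` list.
#' @export
split_scheme <- function(n_repeats = 10L, test_fraction = 0.3, seed = 1L) {
  stopifnot(n_repeats >= 1L, test_fraction > 0, test_fraction < 1)
  structure(list(n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_scheme")
}

#' Gradient-boosted tree hyperparameters
#'
#' Frozen defaults for the boosted-tree learner used by all classification
#' protocols; exposed so the choice is explicit and overridable per run.
#'
#' @param nrounds Boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param eta Learning rate.
#' @return A named list of parameters.
#' @export
ova_params <- function(nrounds = 40L, max_depth = 6L, eta = 0.3) {
  list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
       eta = eta)
}

# stratified train/test split; guarantees every class with >= 2 members is
# represented in both halves
.stratified_split <- function(labels, test_fraction, seed) {
  local_seed(seed, {
    test <- integer()
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      n_test <- round(length(idx) * test_fraction)
      n_test <- max(min(n_test, length(idx) - 1L), if (length(idx) >= 2L) 1L else 0L)
      if (n_test > 0L) test <- c(test, sample(idx, n_test))
    }
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

.fit_gbt <- function(X, y, params, seed) {
  if (ncol(X) == 0L) stopf("cannot fit a classifier on a dataset with no features")
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = params$max_depth,
                  eta = params$eta, nthread = 1L, seed = as.integer(seed)),
    data = dtrain, nrounds = params$nrounds, verbose = 0
  )
}

# gain importances; a booster that never split yields an empty table
.gbt_importance <- function(bst) {
  tryCatch(xgboost::xgb.importance(model = bst),
           error = function(e) data.frame(Feature = character(),
                                          Gain = numeric()))
}

#' Classification metrics from a confusion matrix
#'
#' Precision `P = tp / (tp + fp)`, recall `R = tp / (tp + fn)` (each 0 when
#' its denominator is 0) and their harmonic mean `F1 = 2 P R / (P + R)` (0
#' when `P + R = 0`, i.e. when either precision or recall is zero).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; their total must be > 0.
#' @return A `classification_metrics` list: `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
#' @examples
#' compute_metrics(tp = 3, fp = 2, tn = 10, fn = 7)
compute_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (any(c(tp, fp, tn, fn) < 0) || total == 0) {
    stopf("confusion counts must be non-negative with a positive total")
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(accuracy = (tp + tn) / total, precision = p, recall = r,
                 f1 = f1),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

.metrics_from_pred <- function(pred, truth) {
  compute_metrics(tp = sum(pred == 1 & truth == 1),
                  fp = sum(pred == 1 & truth == 0),
                  tn = sum(pred == 0 & truth == 0),
                  fn = sum(pred == 0 & truth == 1))
}

#' Cancer types large enough for the classification task
#'
#' @param clinical Clinical data frame.
#' @param min_cohort Minimum cohort size; only types with strictly more
#'   patients are included (default 200).
#' @return Character vector of included cancer types.
#' @export
included_cancer_types <- function(clinical, min_cohort = 200L) {
  sizes <- table(clinical$cancer_type)
  sort(names(sizes)[sizes > min_cohort])
}

#' One-vs-all label vector for a cancer type
#'
#' Patients of `cancer_type` are positive (1); all other patients in
#' `clinical` are pooled as negatives (0). Types whose cohort does not exceed
#' `min_cohort` are skipped.
#'
#' @param clinical Clinical data frame (restrict beforehand to the included
#'   types).
#' @param cancer_type Positive class.
#' @param min_cohort Cohort-size threshold (default 200; the type must have
#'   strictly more patients).
#' @return Named integer 0/1 vector over `clinical$patient_id`, or `NULL`
#'   (with a message) when the cohort is too small.
#' @export
make_ova_labels <- function(clinical, cancer_type, min_cohort = 200L) {
  n_pos <- sum(clinical$cancer_type == cancer_type)
  if (n_pos <= min_cohort) {
    message(sprintf("skipping %s: cohort size %d <= %d",
                    cancer_type, n_pos, min_cohort))
    return(NULL)
  }
  stats::setNames(as.integer(clinical$cancer_type == cancer_type),
                  clinical$patient_id)
}

.label_vector <- function(features, labels) {
  X <- if (inherits(features, "feature_matrix")) features$values else features
  if (!is.null(names(labels))) {
    if (!all(rownames(X) %in% names(labels))) {
      stopf("labels are missing for some patients")
    }
    labels <- labels[rownames(X)]
  }
  list(X = X, y = as.integer(labels))
}

#' Train a one-vs-all classifier under the repeated-split protocol
#'
#' Fits a gradient-boosted tree ensemble on each of `n_repeats` stratified
#' 0.7/0.3 splits, evaluates on the held-out patients, and averages metrics
#' and gain-based feature importances across the repeats. Deterministic for a
#' fixed scheme seed.
#'
#' @param features A `feature_matrix` or patients x features sparse matrix.
#' @param labels 0/1 vector (named by patient id, or aligned with rows).
#' @param scheme A [split_scheme()].
#' @param params [ova_params()] hyperparameters.
#' @return An `ova_result`: `per_repeat` metrics data frame, `mean_metrics`,
#'   `importance` (feature_id, importance; descending, ties broken by id).
#' @export
train_ova <- function(features, labels, scheme = split_scheme(),
                      params = ova_params()) {
  lv <- .label_vector(features, labels)
  X <- lv$X; y <- lv$y
  imp_sum <- stats::setNames(numeric(ncol(X)), colnames(X))
  rows <- vector("list", scheme$n_repeats)
  for (r in seq_len(scheme$n_repeats)) {
    seed_r <- scheme$seed + r
    repeat {
      sp <- .stratified_split(y, scheme$test_fraction, seed_r)
      if (length(unique(y[sp$train])) >= 2L) break
      message("degenerate split; resampling with incremented seed")
      seed_r <- seed_r + scheme$n_repeats
    }
    bst <- .fit_gbt(X[sp$train, , drop = FALSE], y[sp$train], params, seed_r)
    pred <- as.integer(stats::predict(bst, xgboost::xgb.DMatrix(
      X[sp$test, , drop = FALSE])) > 0.5)
    m <- .metrics_from_pred(pred, y[sp$test])
    rows[[r]] <- data.frame(repeat_idx = r, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1)
    imp <- .gbt_importance(bst)
    if (nrow(imp)) imp_sum[imp$Feature] <- imp_sum[imp$Feature] + imp$Gain
  }
  per_repeat <- do.call(rbind, rows)
  importance <- data.frame(feature_id = names(imp_sum),
                           importance = unname(imp_sum) / scheme$n_repeats,
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance,
                                 importance$feature_id), , drop = FALSE]
  rownames(importance) <- NULL
  structure(list(
    per_repeat = per_repeat,
    mean_metrics = colMeans(per_repeat[-1L]),
    importance = importance,
    features = if (inherits(features, "feature_matrix")) features$features else NULL,
    scheme = scheme, params = params, n_patients = nrow(X),
    n_features = ncol(X)
  ), class = "ova_result")
}

#' @export
print.ova_result <- function(x, ...) {
  cat(sprintf("<ova_result> %d patients, %d features, %d repeats\n",
              x$n_patients, x$n_features, x$scheme$n_repeats))
  cat(sprintf("mean F1 %.3f (precision %.3f, recall %.3f, accuracy %.3f)\n",
              x$mean_metrics[["f1"]], x$mean_metrics[["precision"]],
              x$mean_metrics[["recall"]], x$mean_metrics[["accuracy"]]))
  invisible(x)
}

#' @export
summary.ova_result <- function(object, ...) {
  cat(sprintf("One-vs-all classifier: %d patients, %d features\n",
              object$n_patients, object$n_features))
  print(object$per_repeat, row.names = FALSE)
  cat("\nTop features:\n")
  print(utils::head(object$importance, 10L), row.names = FALSE)
  invisible(object)
}

#' Label-distribution null model
#'
#' For each repeat, predicts positive for a test patient independently with
#' probability equal to the training-set positive fraction, ignoring the
#' features entirely; metrics are averaged across repeats. Uses the same
#' split seeds as [train_ova()] so comparisons are paired.
#'
#' @inheritParams train_ova
#' @return A list with `per_repeat` and `mean_metrics`, class `null_result`.
#' @export
null_model <- function(labels, scheme = split_scheme()) {
  y <- as.integer(labels)
  rows <- vector("list", scheme$n_repeats)
  for (r in seq_len(scheme$n_repeats)) {
    seed_r <- scheme$seed + r
    sp <- .stratified_split(y, scheme$test_fraction, seed_r)
    p <- mean(y[sp$train])
    pred <- local_seed(seed_r + 10000L,
                       stats::rbinom(length(sp$test), 1L, p))
    m <- .metrics_from_pred(pred, y[sp$test])
    rows[[r]] <- data.frame(repeat_idx = r, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1)
  }
  per_repeat <- do.call(rbind, rows)
  structure(list(per_repeat = per_repeat,
                 mean_metrics = colMeans(per_repeat[-1L]),
                 scheme = scheme),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result> mean F1 %.3f over %d repeats\n",
              x$mean_metrics[["f1"]], x$scheme$n_repeats))
  invisible(x)
}

#' Resolution ablation
#'
#' Trains the same one-vs-all task on nested feature subsets: high-resolution
#' only, high + medium, and all three resolutions, under identical splits
#' (seed-shared) so the comparison is paired.
#'
#' @param features A `feature_matrix` with resolution metadata.
#' @inheritParams train_ova
#' @return Data frame with one row per resolution set and the mean metrics.
#' @export
resolution_ablation <- function(features, labels, scheme = split_scheme(),
                                params = ova_params()) {
  stopifnot(inherits(features, "feature_matrix"))
  sets <- list(HIGH = "HIGH",
               HIGH_MEDIUM = c("HIGH", "MEDIUM"),
               HIGH_MEDIUM_LOW = c("HIGH", "MEDIUM", "LOW"))
  rows <- lapply(names(sets), function(nm) {
    sub <- subset_features(features, features$features$resolution %in% sets[[nm]])
    res <- train_ova(sub, labels, scheme, params)
    data.frame(resolution_set = nm, n_features = ncol(sub$values),
               mean_f1 = res$mean_metrics[["f1"]],
               mean_precision = res$mean_metrics[["precision"]],
               mean_recall = res$mean_metrics[["recall"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Balanced (equal-width) dataset protocol
#'
#' Controls for the category imbalance in feature counts: using only
#' high-resolution features, patients are split into two equal halves; a
#' model trained on the first half ranks each category's features and the top
#' `K` are retained (with `K = "auto"` equal to the size of the smallest
#' category's feature set); the six equal-width datasets (five categories
#' plus their 5K-column concatenation) are then retrained on the second half
#' under the repeated-split scheme.
#'
#' @param datasets Named list of the five single-category `feature_matrix`
#'   objects (any resolutions; high-resolution columns are selected
#'   internally).
#' @param labels 0/1 vector named by patient id.
#' @param scheme A [split_scheme()] (also seeds the half split).
#' @param K Feature budget per category, or `"auto"`.
#' @param params [ova_params()] hyperparameters.
#' @return List with `K`, `selected` (feature ids per dataset), `results`
#'   (`ova_result` per dataset and for `ALL`), and `halves` (patient ids).
#' @export
balanced_protocol <- function(datasets, labels, scheme = split_scheme(),
                              K = "auto", params = ova_params()) {
  high <- lapply(datasets, function(d) {
    subset_features(d, d$features$resolution == "HIGH")
  })
  sizes <- vapply(high, function(d) ncol(d$values), integer(1))
  if (identical(K, "auto")) {
    K <- min(sizes)
  } else if (any(sizes < K)) {
    message(sprintf("feature budget lowered from %d to %d (smallest category)",
                    K, min(sizes)))
    K <- min(sizes)
  }
  patients <- high[[1]]$patients
  y <- as.integer(labels[patients])
  sp <- .stratified_split(y, 0.5, scheme$seed)
  half1 <- patients[sp$test]   # selection half
  half2 <- patients[sp$train]  # evaluation half (sizes differ by at most 1)
  selected <- lapply(high, function(d) {
    X1 <- d$values[half1, , drop = FALSE]
    bst <- .fit_gbt(X1, y[match(half1, patients)], params, scheme$seed)
    imp <- .gbt_importance(bst)
    ranked <- imp$Feature[order(-imp$Gain, imp$Feature)]
    # pad with unused features (by id) so every dataset has exactly K columns
    utils::head(c(ranked, sort(setdiff(colnames(X1), ranked))), K)
  })
  balanced <- lapply(names(high), function(nm) {
    sub <- subset_features(high[[nm]],
                           match(selected[[nm]], high[[nm]]$features$feature_id))
    feature_matrix(sub$values[half2, , drop = FALSE], sub$features, half2)
  })
  names(balanced) <- names(high)
  balanced$ALL <- assemble_dataset(balanced)
  y2 <- stats::setNames(y[match(half2, patients)], half2)
  results <- lapply(balanced, function(d) train_ova(d, y2, scheme, params))
  list(K = K, selected = selected, datasets = balanced, results = results,
       halves = list(selection = half1, evaluation = half2))
}

#' Plan the grid of classification runs
#'
#' One run per (cancer type, dataset) combination; with 19 included cancer
#' types and six datasets this schedules 114 one-vs-all classifiers.
#'
#' @param cancer_types Character vector of included cancer types.
#' @param datasets Character vector of dataset names (default the five
#'   categories plus `"ALL"`).
#' @return Data frame with columns `cancer_type` and `dataset`.
#' @export
plan_classification_runs <- function(cancer_types,
                                     datasets = c(mutation_categories(), "ALL")) {
  out <- expand.grid(cancer_type = cancer_types, dataset = datasets,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out[order(out$cancer_type, out$dataset), , drop = FALSE]
}
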