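# Survival labels, feature selection, random survival forests under the
# repeated-split protocol, and time-dependent AUC against a null model.

#' Default evaluation time grid (days since diagnosis)
#'
#' Ten evaluation times from 100 to 4500 days; beyond 4500 days follow-up
#' data are scarce and the analysis stops.
#'
#' @return Integer vector of evaluation days.
#' @export
survival_time_grid <- function() {
  c(100L, 500L, 1000L, 1500L, 2000L, 2500L, 3000L, 3500L, 4000L, 4500L)
}

#' Random survival forest configuration
#'
#' @param n_trees Trees per forest (default 60).
#' @param max_depth Maximum tree depth (default 32).
#' @param n_repeats Train/test repetitions (default 5).
#' @param test_fraction Held-out fraction (default 0.3).
#' @param seed Base seed.
#' @return An `rsf_config` list. Splits use the log-rank rule on
#'   Kaplan-Meier estimates.
#' @export
rsf_config <- function(n_trees = 60L, max_depth = 32L, n_repeats = 5L,
                       test_fraction = 0.3, seed = 1L) {
  stopifnot(n_trees >= 1L, max_depth >= 1L, n_repeats >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "rsf_config")
}

#' Build survival labels from a clinical table
#'
#' Deceased patients get event 1 at `days_to_death`; alive patients are
#' censored at `days_to_last_followup`. Patients with no available
#' information after diagnosis (missing or non-positive times) are excluded,
#' as are patients who died less than `min_days` days after diagnosis (a
#' death at exactly `min_days` is kept). All cancer types are pooled into a
#' single cohort.
#'
#' @param clinical Clinical data frame.
#' @param min_days Minimum days-to-death for deceased patients (default 20).
#' @return List with `labels` (patient_id, event, time) and `exclusions`
#'   (named counts per reason).
#' @export
build_survival_labels <- function(clinical, min_days = 20L) {
  deceased <- clinical$vital_status == "deceased"
  time <- ifelse(deceased, clinical$days_to_death,
                 clinical$days_to_last_followup)
  no_status <- is.na(clinical$vital_status)
  no_time <- !no_status & (is.na(time) | time <= 0)
  early_death <- !no_status & !no_time & deceased & time < min_days
  keep <- !(no_status | no_time | early_death)
  list(
    labels = data.frame(
      patient_id = clinical$patient_id[keep],
      event = as.integer(deceased[keep]),
      time = as.numeric(time[keep]),
      stringsAsFactors = FALSE
    ),
    exclusions = c(no_vital_status = sum(no_status),
                   no_followup = sum(no_time),
                   early_death = sum(early_death))
  )
}

#' Select the survival feature subset
#'
#' Keeps all low-resolution features plus the `n_high` high-resolution
#' features corresponding to the most prevalent mutations (largest carrier
#' counts; ties at the cutoff broken by feature id). Medium-resolution
#' features are excluded.
#'
#' @param features A `feature_matrix`.
#' @param n_high Number of high-resolution features to keep (default 5000;
#'   all are kept, with a message, when fewer exist).
#' @return A `feature_matrix` subset.
#' @export
select_survival_features <- function(features, n_high = 5000L) {
  res <- features$features$resolution
  high_idx <- which(res == "HIGH")
  if (length(high_idx) > n_high) {
    carriers <- Matrix::colSums(features$values[, high_idx, drop = FALSE] > 0)
    ord <- order(-carriers, features$features$feature_id[high_idx])
    high_idx <- high_idx[ord[seq_len(n_high)]]
  } else if (length(high_idx) < n_high) {
    message(sprintf("only %d high-resolution features available (requested %d)",
                    length(high_idx), n_high))
  }
  keep <- sort(c(which(res == "LOW"), high_idx))
  subset_features(features, keep)
}

# step-function lookup of survival curves at grid times
.curves_at <- function(surv, death_times, grid) {
  sapply(grid, function(t) {
    k <- findInterval(t, death_times)
    if (k == 0L) rep(1, nrow(surv)) else surv[, k]
  })
}

#' Fit random survival forests under the repeated-split protocol
#'
#' Per repetition, patients are split (stratified by event status) into
#' 0.7/0.3 training and test sets, a random survival forest (log-rank
#' splitting) is grown on the training patients, and held-out survival curves
#' are evaluated on the time grid. A patient's final curve is the average
#' over the repetitions in which they were held out. Permutation feature
#' importances are averaged across repetitions.
#'
#' @param features A `feature_matrix` (e.g. from
#'   [select_survival_features()]); cancer type is never provided as a
#'   feature.
#' @param labels Survival labels data frame (`patient_id`, `event`, `time`).
#' @param config An [rsf_config()].
#' @param grid Evaluation days (default [survival_time_grid()]).
#' @return An `rsf_result`: `surv` (patients x grid matrix of averaged
#'   survival probabilities, `NA` for patients never held out), `grid`,
#'   `labels`, `importance` (feature_id, importance), `config`.
#' @export
fit_rsf <- function(features, labels, config = rsf_config(),
                    grid = survival_time_grid()) {
  idx <- match(labels$patient_id, features$patients)
  if (anyNA(idx)) stopf("labels contain patients absent from the feature matrix")
  X <- features$values[idx, , drop = FALSE]
  df <- as.data.frame(as.matrix(X))
  names(df) <- paste0("f", seq_len(ncol(df)))  # syntactic names for ranger
  feature_ids <- features$features$feature_id
  df$.time <- labels$time
  df$.event <- labels$event
  n <- nrow(df)
  surv_sum <- matrix(0, n, length(grid))
  surv_n <- matrix(0L, n, length(grid))
  imp_sum <- stats::setNames(numeric(ncol(X)), names(df)[seq_len(ncol(X))])
  for (r in seq_len(config$n_repeats)) {
    seed_r <- config$seed + r
    repeat {
      sp <- .stratified_split(labels$event, config$test_fraction, seed_r)
      if (sum(labels$event[sp$train]) > 0L) break
      message("no events in training split; resampling with incremented seed")
      seed_r <- seed_r + config$n_repeats
    }
    fit <- ranger::ranger(
      survival::Surv(.time, .event) ~ ., data = df[sp$train, , drop = FALSE],
      num.trees = config$n_trees, max.depth = config$max_depth,
      splitrule = "logrank", importance = "permutation",
      seed = seed_r, num.threads = 1L
    )
    pred <- stats::predict(fit, data = df[sp$test, , drop = FALSE],
                           num.threads = 1L)
    s <- .curves_at(pred$survival, pred$unique.death.times, grid)
    surv_sum[sp$test, ] <- surv_sum[sp$test, ] + s
    surv_n[sp$test, ] <- surv_n[sp$test, ] + 1L
    imp_sum <- imp_sum + fit$variable.importance[names(imp_sum)]
  }
  surv <- ifelse(surv_n > 0, surv_sum / surv_n, NA_real_)
  rownames(surv) <- labels$patient_id
  colnames(surv) <- grid
  importance <- data.frame(
    feature_id = feature_ids,
    importance = unname(imp_sum) / config$n_repeats,
    stringsAsFactors = FALSE
  )
  importance <- importance[order(-importance$importance,
                                 importance$feature_id), , drop = FALSE]
  rownames(importance) <- NULL
  structure(list(surv = surv, grid = grid, labels = labels,
                 importance = importance, config = config,
                 n_features = ncol(X)),
            class = "rsf_result")
}

#' @export
print.rsf_result <- function(x, ...) {
  cat(sprintf("<rsf_result> %d patients, %d features, %d trees x %d repeats\n",
              nrow(x$surv), x$n_features, x$config$n_trees,
              x$config$n_repeats))
  auc <- time_dependent_auc(x)
  cat("AUC(t):\n")
  print(round(auc, 3))
  invisible(x)
}

# cumulative/dynamic AUC for one time point from risk scores
.auc_at <- function(risk, event, time, t) {
  cases <- which(event == 1 & time <= t & !is.na(risk))
  controls <- which(time > t & !is.na(risk))
  if (!length(cases) || !length(controls)) return(NA_real_)
  cmp <- outer(risk[cases], risk[controls],
               function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Time-dependent (cumulative/dynamic) AUC
#'
#' At each grid time `t`, the risk score is `1 - S_i(t)`; cases are patients
#' with an event by `t`, controls are patients still at risk beyond `t`
#' (patients censored before `t` are omitted from both sets), and the AUC is
#' the fraction of case-control pairs where the case has the higher risk,
#' ties counting one half. No inverse-probability-of-censoring weighting is
#' applied.
#'
#' @param x An `rsf_result`, or a patients x times matrix of survival
#'   probabilities.
#' @param labels Survival labels (taken from `x` when it is an
#'   `rsf_result`).
#' @param grid Evaluation days (taken from `x` when available).
#' @return Named numeric vector of AUC values (`NA` where no comparable
#'   pairs exist).
#' @export
time_dependent_auc <- function(x, labels = NULL, grid = NULL) {
  if (inherits(x, "rsf_result")) {
    labels <- labels %||% x$labels
    grid <- grid %||% x$grid
    surv <- x$surv
  } else {
    surv <- x
    if (is.null(grid)) grid <- as.numeric(colnames(surv))
  }
  risk <- 1 - surv
  out <- vapply(seq_along(grid), function(k) {
    .auc_at(risk[, k], labels$event, labels$time, grid[k])
  }, numeric(1))
  stats::setNames(out, grid)
}

#' Null survival model AUC
#'
#' Risk scores drawn independently of all covariates (uniform per patient);
#' the expected AUC is 0.5 at every time point. Reported as the mean over
#' repetitions.
#'
#' @param labels Survival labels data frame.
#' @param grid Evaluation days.
#' @param seed Base seed.
#' @param n_reps Repetitions (default 100).
#' @return Named numeric vector of mean null AUC per grid time.
#' @export
null_survival_auc <- function(labels, grid = survival_time_grid(),
                              seed = 1L, n_reps = 100L) {
  acc <- matrix(NA_real_, n_reps, length(grid))
  for (r in seq_len(n_reps)) {
    risk <- local_seed(seed + r, stats::runif(nrow(labels)))
    acc[r, ] <- vapply(grid, function(t) {
      .auc_at(risk, labels$event, labels$time, t)
    }, numeric(1))
  }
  stats::setNames(colMeans(acc, na.rm = TRUE), grid)
}

#' Feature importance ranking from a fitted survival forest
#'
#' Permutation importances (degradation of out-of-bag concordance when a
#' feature is permuted), averaged over the protocol's repetitions; the
#' result feeds the gene-ranking analyses unchanged.
#'
#' @param x An `rsf_result`.
#' @return Data frame `feature_id`, `importance`, descending.
#' @export
rsf_feature_importance <- function(x) {
  stopifnot(inherits(x, "rsf_result"))
  x$importance
}
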