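# End-to-end orchestration: one config drives preprocessing, the
# classification branch, the ranking/similarity/burden analyses and the
# survival branch, writing machine-readable tables.

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults mirror the
#' protocol constants used throughout the package (cohort threshold 200,
#' 10 x 0.7/0.3 splits, Jaccard 100 x 5, misclassification 250 x 10, RSF 60
#' trees depth 32 x 5 repeats, 5000 high-resolution survival features).
#'
#' @param mutations,clinical In-memory input tables, or `NULL` to read from
#'   `maf_path` / `clinical_path`.
#' @param annotation A `gene_annotation` (required for medium-resolution
#'   features).
#' @param maf_path,clinical_path Input file paths (used when the in-memory
#'   tables are `NULL`).
#' @param out_dir Output directory for the report bundle (`NULL` = do not
#'   write files).
#' @param min_cohort Cohort-size threshold for the classification task.
#' @param scheme [split_scheme()] for all classification protocols.
#' @param params [ova_params()] boosted-tree hyperparameters.
#' @param jaccard_sample,jaccard_reps Jaccard protocol sample size and
#'   repetitions.
#' @param misclass_sample,misclass_reps Misclassification protocol sample
#'   size and repetitions.
#' @param rsf [rsf_config()] for the survival branch.
#' @param n_high High-resolution features kept for survival.
#' @param grid Survival evaluation days.
#' @param topk Top-feature list length for ranking analyses.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(mutations = NULL, clinical = NULL, annotation,
                       maf_path = NULL, clinical_path = NULL, out_dir = NULL,
                       min_cohort = 200L, scheme = NULL, params = ova_params(),
                       jaccard_sample = 100L, jaccard_reps = 5L,
                       misclass_sample = 250L, misclass_reps = 10L,
                       rsf = NULL, n_high = 5000L,
                       grid = survival_time_grid(), topk = 10L, seed = 1L) {
  structure(list(
    mutations = mutations, clinical = clinical, annotation = annotation,
    maf_path = maf_path, clinical_path = clinical_path, out_dir = out_dir,
    min_cohort = as.integer(min_cohort),
    scheme = scheme %||% split_scheme(seed = seed),
    params = params,
    jaccard_sample = as.integer(jaccard_sample),
    jaccard_reps = as.integer(jaccard_reps),
    misclass_sample = as.integer(misclass_sample),
    misclass_reps = as.integer(misclass_reps),
    rsf = rsf %||% rsf_config(seed = seed + 500L),
    n_high = as.integer(n_high), grid = grid, topk = as.integer(topk),
    seed = as.integer(seed)
  ), class = "run_config")
}

# polynomial rolling hash of the deparsed config, for provenance stamping
.config_hash <- function(config) {
  skip <- c("mutations", "clinical", "annotation",
            "maf_path", "clinical_path", "out_dir")
  bytes <- utf8ToInt(paste(deparse(config[setdiff(names(config), skip)]),
                           collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_tsv <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (patient filters, category sorting, the six
#' datasets), the classification branch (one-vs-all models and null models
#' per cancer type and dataset), the ranking, similarity and burden
#' analyses, and the survival branch, from a single [run_config()]. Tables
#' are written to `config$out_dir` (when set) stamped with the master seed
#' and a config hash; identical configs produce identical bundles. A stage
#' failure is caught and recorded, yielding a partial bundle with status
#' `"partial"`.
#'
#' @param config A [run_config()].
#' @return A report bundle list: `metrics`, `rankings`, `top_genes`,
#'   `membership`, `cross_model`, `improvement`, `pairs`, `correlations`,
#'   `survival`, `status`, `errors`, `seed`, `config_hash`, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  errors <- character()
  stage <- function(name, expr) {
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      errors[[length(errors) + 1L]] <<- sprintf("%s: %s", name,
                                                conditionMessage(e))
      NULL
    })
  }
  if (!is.null(config$out_dir) &&
      !dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }

  prep <- stage("preprocess", {
    mutations <- config$mutations %||% read_maf(config$maf_path)
    clinical <- config$clinical %||% read_clinical(config$clinical_path)
    flt <- filter_patients(mutations, clinical)
    flt$mutations$category <- categorize(flt$mutations$variant_classification)
    flt
  })
  if (is.null(prep)) {
    return(invisible(list(status = "fatal", errors = errors)))
  }
  patients <- sort(unique(prep$clinical$patient_id))

  datasets <- stage("features", {
    build_datasets(prep$mutations, config$annotation, patients)
  })

  types <- included_cancer_types(prep$clinical, config$min_cohort)
  dataset_names <- c(mutation_categories(), "ALL")
  plan <- plan_classification_runs(types, dataset_names)

  classification <- stage("classification", {
    results <- list()
    metrics_rows <- list()
    for (ty in types) {
      labels <- make_ova_labels(prep$clinical, ty, config$min_cohort)
      null_res <- null_model(labels[datasets[[1]]$patients], config$scheme)
      metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
        cancer_type = ty, dataset = "NULL", mean_f1 = null_res$mean_metrics[["f1"]],
        mean_precision = null_res$mean_metrics[["precision"]],
        mean_recall = null_res$mean_metrics[["recall"]],
        mean_accuracy = null_res$mean_metrics[["accuracy"]],
        stringsAsFactors = FALSE
      )
      for (ds in dataset_names) {
        res <- train_ova(datasets[[ds]], labels, config$scheme, config$params)
        results[[ty]][[ds]] <- res
        metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
          cancer_type = ty, dataset = ds, mean_f1 = res$mean_metrics[["f1"]],
          mean_precision = res$mean_metrics[["precision"]],
          mean_recall = res$mean_metrics[["recall"]],
          mean_accuracy = res$mean_metrics[["accuracy"]],
          stringsAsFactors = FALSE
        )
      }
    }
    list(results = results, metrics = do.call(rbind, metrics_rows))
  })

  rankings <- stage("rankings", {
    res <- classification$results
    gene_rankings <- list(); top_lists <- list()
    for (ty in types) {
      for (ds in dataset_names) {
        fmap <- feature_gene_map(datasets[[ds]]$features)
        gene_rankings[[ty]][[ds]] <-
          derive_gene_ranking(res[[ty]][[ds]]$importance, fmap)
        top_lists[[ty]][[ds]] <-
          top_genes(res[[ty]][[ds]]$importance, fmap, config$topk)
      }
    }
    single <- lapply(gene_rankings, function(x) x[mutation_categories()])
    membership <- top_gene_membership(
      lapply(top_lists, function(x) x[mutation_categories()]))
    cross <- if (length(types) >= 1L) {
      cross_model_rank_correlation(single)
    }
    all_rank <- lapply(types, function(ty) {
      classification$results[[ty]][["ALL"]]$importance
    })
    names(all_rank) <- types
    type_dist <- topk_type_distribution(all_rank, datasets[["ALL"]]$features,
                                        config$topk)
    poly <- polymorphism_enrichment(all_rank, datasets[["ALL"]]$features,
                                    config$topk)
    counts <- tapply(prep$mutations$gene_symbol[prep$mutations$category != "EXCLUDED"],
                     prep$mutations$gene_symbol[prep$mutations$category != "EXCLUDED"],
                     length)
    gc_map <- stats::setNames(as.numeric(counts), names(counts))
    count_corr <- mutation_count_rank_correlation(
      lapply(gene_rankings, `[[`, "ALL"), gc_map)
    list(gene_rankings = gene_rankings, top_lists = top_lists,
         membership = membership, cross_model = cross,
         type_distribution = type_dist, polymorphism = poly,
         count_correlation = count_corr)
  })

  improvement <- stage("improvement", {
    rows <- lapply(types, function(ty) {
      m <- classification$metrics
      f1_all <- m$mean_f1[m$cancer_type == ty & m$dataset == "ALL"]
      f1_ns <- m$mean_f1[m$cancer_type == ty & m$dataset == "NON_SILENT"]
      pats <- prep$clinical$patient_id[prep$clinical$cancer_type == ty]
      b_all <- mutational_burden(prep$mutations, pats)
      b_ns <- mutational_burden(prep$mutations, pats, "NON_SILENT")
      mb <- mb_increase(b_all, b_ns)
      data.frame(cancer_type = ty, f1_all = f1_all, f1_ns = f1_ns,
                 f1_improvement = f1_improvement(f1_all, f1_ns),
                 mb_increase = mb$mb_increase,
                 n_excluded = mb$n_excluded, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    corr <- if (nrow(out) >= 3L) improvement_burden_correlation(out)
    list(records = out, correlation = corr)
  })

  pairs <- stage("similarity", {
    if (length(types) < 2L) return(NULL)
    combos <- utils::combn(types, 2L)
    rows <- lapply(seq_len(ncol(combos)), function(k) {
      a <- combos[1L, k]; b <- combos[2L, k]
      jp <- jaccard_pair_protocol(datasets[["ALL"]], prep$clinical, a, b,
                                  config$jaccard_sample, config$jaccard_reps,
                                  seed = config$seed + 100L + k)
      mp <- misclassification_protocol(datasets[["ALL"]], prep$clinical, a, b,
                                       config$misclass_sample,
                                       config$misclass_reps,
                                       seed = config$seed + 200L + k,
                                       params = config$params)
      data.frame(type_a = a, type_b = b, J = jp$J, M = mp$M,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    corr <- if (nrow(out) >= 3L) similarity_vs_misclassification(out)
    list(pairs = out, correlation = corr)
  })

  surv <- stage("survival", {
    if (all(is.na(prep$clinical$vital_status))) return(NULL)
    lab <- build_survival_labels(prep$clinical)
    feats <- select_survival_features(datasets[["ALL"]], config$n_high)
    fit <- fit_rsf(feats, lab$labels, config$rsf, config$grid)
    auc <- time_dependent_auc(fit)
    null_auc <- null_survival_auc(lab$labels, config$grid,
                                  seed = config$seed + 900L)
    list(fit = fit, auc = auc, null_auc = null_auc,
         exclusions = lab$exclusions)
  })

  bundle <- list(
    plan = plan,
    metrics = classification$metrics,
    rankings = rankings,
    improvement = improvement,
    pairs = pairs,
    survival = surv,
    status = if (length(errors)) "partial" else "ok",
    errors = errors,
    seed = config$seed,
    config_hash = .config_hash(config),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(config$out_dir)) {
    stamp <- function(df) {
      df$seed <- config$seed; df$config_hash <- bundle$config_hash; df
    }
    .write_tsv(stamp(classification$metrics), config$out_dir, "metrics.tsv")
    .write_tsv(stamp(improvement$records), config$out_dir, "improvement.tsv")
    if (!is.null(pairs)) {
      .write_tsv(stamp(pairs$pairs), config$out_dir, "pairs.tsv")
    }
    if (!is.null(surv)) {
      auc_df <- data.frame(days = config$grid, auc = unname(surv$auc),
                           null_auc = unname(surv$null_auc))
      .write_tsv(stamp(auc_df), config$out_dir, "survival_auc.tsv")
    }
    if (!is.null(rankings)) {
      .write_tsv(stamp(rankings$type_distribution), config$out_dir,
                 "topk_type_distribution.tsv")
      export_ranked_gene_lists(rankings$gene_rankings,
                               file.path(config$out_dir, "gene_lists"))
    }
  }
  invisible(bundle)
}

#' Export ranked gene lists
#'
#' Writes one plain-text file per (cancer type, model): gene symbols in rank
#' order, one per line — the ranked-list input format of GO-enrichment tools.
#'
#' @param gene_rankings Nested list: `gene_rankings[[cancer_type]][[model]]`
#'   is a `gene_ranking` or a character vector of gene symbols in rank
#'   order.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
export_ranked_gene_lists <- function(gene_rankings, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  for (ct in names(gene_rankings)) {
    for (md in names(gene_rankings[[ct]])) {
      gr <- gene_rankings[[ct]][[md]]
      symbols <- if (is.data.frame(gr)) gr$gene_symbol else as.character(gr)
      path <- file.path(out_dir, sprintf("%s_%s.txt", ct, md))
      writeLines(symbols, path)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}
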