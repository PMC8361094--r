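# Gene rankings derived from feature importance rankings, and the analyses
# built on them: top-k composition and enrichment, polymorphism-type
# enrichment, cross-model rank correlations, top-gene membership and the
# mutation-count/rank correlation.

#' Derive a gene ranking from a feature importance ranking
#'
#' Features with zero importance are discarded; the remaining features are
#' assigned to their genes while keeping the importance order, and only the
#' best (first) occurrence of each gene is kept. The most important gene is
#' ranked 0.
#'
#' @param importance Data frame with columns `feature_id` and `importance`,
#'   sorted by descending importance (ties broken by feature id); e.g. the
#'   `importance` element of an [train_ova()] result.
#' @param feature_genes Named character vector mapping feature ids to gene
#'   symbols (every ranked feature must be mapped).
#' @return A `gene_ranking` data frame with columns `gene_symbol` and `rank`
#'   (0 = most important).
#' @export
#' @examples
#' imp <- data.frame(feature_id = c("f1", "f2", "f3"),
#'                   importance = c(0.5, 0.3, 0.2))
#' derive_gene_ranking(imp, c(f1 = "A", f2 = "B", f3 = "A"))
derive_gene_ranking <- function(importance, feature_genes) {
  imp <- importance[importance$importance > 0, , drop = FALSE]
  imp <- imp[order(-imp$importance, imp$feature_id), , drop = FALSE]
  unmapped <- setdiff(imp$feature_id, names(feature_genes))
  if (length(unmapped)) {
    stopf("feature id(s) not mapped to a gene: %s",
          paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  genes <- unname(feature_genes[imp$feature_id])
  keep <- !duplicated(genes)
  out <- data.frame(gene_symbol = genes[keep],
                    rank = seq_len(sum(keep)) - 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_ranking", "data.frame")
  out
}

# feature id -> gene map from feature_matrix metadata
#' Feature-to-gene map from feature metadata
#'
#' @param features Feature metadata data frame (`features` element of a
#'   `feature_matrix`) with `feature_id` and `gene_symbol`.
#' @return Named character vector mapping feature ids to gene symbols.
#' @export
feature_gene_map <- function(features) {
  stats::setNames(features$gene_symbol, features$feature_id)
}

# joins an importance ranking with feature metadata, positive importance only
.ranked_metadata <- function(importance, features) {
  imp <- importance[importance$importance > 0, , drop = FALSE]
  cbind(imp, features[match(imp$feature_id, features$feature_id),
                      c("resolution", "category", "gene_symbol",
                        "variant_type"), drop = FALSE])
}

#' Mutation-category composition of top-ranked features
#'
#' For each model's feature ranking, computes the fraction of each mutation
#' category among the `k` top-ranked (positive-importance) features, averages
#' the fractions across models (cancer types), and reports the enrichment of
#' each category relative to its share of the whole dataset.
#'
#' @param rankings Named list (one per cancer type) of importance data frames
#'   (`feature_id`, `importance`).
#' @param features Feature metadata of the dataset the rankings came from.
#' @param k Number of top features (default 10).
#' @return Data frame: `category`, `topk_fraction` (mean across models),
#'   `dataset_fraction`, `enrichment`.
#' @export
topk_type_distribution <- function(rankings, features, k = 10L) {
  cats <- mutation_categories()
  topk <- sapply(rankings, function(rk) {
    meta <- .ranked_metadata(rk, features)
    if (nrow(meta) < k) {
      warnf("ranking has only %d positive-importance features (k = %d)",
            nrow(meta), k)
    }
    top <- utils::head(meta, k)
    as.numeric(table(factor(top$category, levels = cats)) / nrow(top))
  })
  dataset_fraction <- as.numeric(
    table(factor(features$category, levels = cats)) / nrow(features))
  data.frame(
    category = cats,
    topk_fraction = rowMeans(topk),
    dataset_fraction = dataset_fraction,
    enrichment = rowMeans(topk) / dataset_fraction,
    stringsAsFactors = FALSE
  )
}

#' Polymorphism-type enrichment among top-ranked features
#'
#' Among high-resolution features only (low/medium features carry no
#' polymorphism type and are excluded from numerator and denominator),
#' compares the SNP/DEL/INS composition of the `k` top-ranked features with
#' the composition of the whole dataset.
#'
#' @inheritParams topk_type_distribution
#' @return Data frame: `variant_type`, `topk_fraction`, `dataset_fraction`,
#'   `enrichment` (all `NA` with zero `n_topk` when no high-resolution
#'   feature reaches the top `k`).
#' @export
polymorphism_enrichment <- function(rankings, features, k = 10L) {
  vts <- c("SNP", "DEL", "INS")
  high <- features[features$resolution == "HIGH", , drop = FALSE]
  dataset_fraction <- as.numeric(
    table(factor(high$variant_type, levels = vts)) / max(nrow(high), 1L))
  per_model <- sapply(rankings, function(rk) {
    meta <- .ranked_metadata(rk, features)
    top_high <- utils::head(meta, k)
    top_high <- top_high[top_high$resolution == "HIGH", , drop = FALSE]
    if (!nrow(top_high)) return(rep(NA_real_, length(vts)))
    as.numeric(table(factor(top_high$variant_type, levels = vts)) /
                 nrow(top_high))
  })
  topk_fraction <- rowMeans(per_model, na.rm = TRUE)
  n_models <- sum(!is.na(per_model[1L, ]))
  data.frame(
    variant_type = vts,
    topk_fraction = if (n_models) topk_fraction else rep(NA_real_, 3L),
    dataset_fraction = dataset_fraction,
    enrichment = if (n_models) topk_fraction / dataset_fraction else
      rep(NA_real_, 3L),
    n_models = n_models,
    stringsAsFactors = FALSE
  )
}

#' Cross-model Spearman correlation of gene rankings
#'
#' For every cancer type and every pair of single-category models, genes
#' outside the intersection of the two gene ranking lists are discarded and
#' Spearman's rho is computed on the remaining ranks; rho and p are then
#' averaged across cancer types. The all-features model is excluded by
#' construction (only the supplied single-category rankings are compared).
#'
#' @param rankings Nested list: `rankings[[cancer_type]][[model]]` is a
#'   `gene_ranking` (see [derive_gene_ranking()]).
#' @param min_overlap Minimum intersection size for a pair to contribute
#'   (default 3; smaller intersections are skipped with a message).
#' @return List with matrices `rho` (mean Spearman rho), `p` (mean p-value),
#'   `fisher_p` (Fisher-combined p) and `n_pairs` (cancer types contributing
#'   to each cell).
#' @export
cross_model_rank_correlation <- function(rankings, min_overlap = 3L) {
  models <- names(rankings[[1]])
  m <- length(models)
  rho_sum <- p_sum <- n_mat <- chisq <- matrix(
    0, m, m, dimnames = list(models, models))
  for (ct in names(rankings)) {
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        a <- rankings[[ct]][[models[i]]]
        b <- rankings[[ct]][[models[j]]]
        shared <- intersect(a$gene_symbol, b$gene_symbol)
        if (length(shared) < min_overlap) {
          message(sprintf("%s: %s vs %s intersection has %d genes; skipped",
                          ct, models[i], models[j], length(shared)))
          next
        }
        st <- spearman_stat(a$rank[match(shared, a$gene_symbol)],
                            b$rank[match(shared, b$gene_symbol)])
        if (is.na(st$rho)) next
        rho_sum[i, j] <- rho_sum[i, j] + st$rho
        p_sum[i, j] <- p_sum[i, j] + st$p
        chisq[i, j] <- chisq[i, j] - 2 * log(max(st$p, 1e-300))
        n_mat[i, j] <- n_mat[i, j] + 1L
      }
    }
  }
  sym <- function(x) {x[lower.tri(x)] <- t(x)[lower.tri(x)]; x}
  rho <- sym(ifelse(n_mat > 0, rho_sum / n_mat, NA_real_))
  p <- sym(ifelse(n_mat > 0, p_sum / n_mat, NA_real_))
  fisher <- sym(ifelse(n_mat > 0,
                       stats::pchisq(chisq, df = 2 * n_mat, lower.tail = FALSE),
                       NA_real_))
  diag(rho) <- 1; diag(p) <- 0; diag(fisher) <- 0
  list(rho = rho, p = p, fisher_p = fisher, n_pairs = sym(n_mat))
}

#' Top genes from a feature ranking
#'
#' Collapses the `k` top-ranked (positive-importance) features to genes while
#' preserving order; the list may contain fewer than `k` genes when several
#' top features share a gene (no padding is applied).
#'
#' @inheritParams derive_gene_ranking
#' @param k Number of top features (default 10).
#' @return Character vector of gene symbols in rank order.
#' @export
top_genes <- function(importance, feature_genes, k = 10L) {
  gr <- derive_gene_ranking(utils::head(
    importance[importance$importance > 0, , drop = FALSE], k), feature_genes)
  gr$gene_symbol
}

#' Top-gene membership matrix
#'
#' For each single-category model, counts in how many cancer types' top-`k`
#' gene lists each gene appears; cells are bounded by the number of cancer
#' types.
#'
#' @param top_gene_lists Nested list:
#'   `top_gene_lists[[cancer_type]][[model]]` is a character vector of top
#'   genes (see [top_genes()]).
#' @return Integer matrix, genes x models.
#' @export
top_gene_membership <- function(top_gene_lists) {
  models <- names(top_gene_lists[[1]])
  genes <- sort(unique(unlist(top_gene_lists)))
  out <- matrix(0L, length(genes), length(models),
                dimnames = list(genes, models))
  for (ct in names(top_gene_lists)) {
    for (md in models) {
      hit <- unique(top_gene_lists[[ct]][[md]])
      out[hit, md] <- out[hit, md] + 1L
    }
  }
  out
}

#' Correlation between per-gene mutation counts and gene rankings
#'
#' Spearman correlation, per cancer type, between the total number of
#' mutations per gene in the cohort and the gene's importance (ranks are
#' reversed so that a positive rho means more-mutated genes rank as more
#' important).
#'
#' @param rankings Named list (per cancer type) of `gene_ranking` objects.
#' @param gene_counts Named numeric vector: total mutation count per gene,
#'   computed over the same cohort as the rankings.
#' @return List with `per_type` (data frame of rho and p per cancer type)
#'   and `mean_rho`.
#' @export
mutation_count_rank_correlation <- function(rankings, gene_counts) {
  rows <- lapply(names(rankings), function(ct) {
    gr <- rankings[[ct]]
    counts <- gene_counts[gr$gene_symbol]
    st <- spearman_stat(as.numeric(counts), -gr$rank)
    data.frame(cancer_type = ct, rho = st$rho, p = st$p,
               n_genes = nrow(gr), stringsAsFactors = FALSE)
  })
  per_type <- do.call(rbind, rows)
  list(per_type = per_type, mean_rho = mean(per_type$rho, na.rm = TRUE))
}
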