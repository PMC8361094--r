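# Build the three feature resolutions per mutation category and the six
# datasets used by the classification and survival tasks.

# feature matrix with zero features over a fixed patient axis
.empty_fm <- function(patients) {
  feature_matrix(
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(length(patients), 0L)),
    data.frame(feature_id = character(0), resolution = character(0),
               category = character(0), gene_symbol = character(0),
               stringsAsFactors = FALSE),
    patients
  )
}

.categorized <- function(mutations, category_map) {
  if (!"category" %in% names(mutations)) {
    mutations$category <- categorize(mutations$variant_classification, category_map)
  }
  mutations[mutations$category != "EXCLUDED", , drop = FALSE]
}

#' Build low-resolution (whole-gene count) features
#'
#' One feature per gene carrying at least one retained mutation of the
#' category anywhere in the cohort; the value for a patient is the number of
#' that patient's mutations of the category in the gene.
#'
#' @param mutations Mutation data frame (internal layout).
#' @param category One of [mutation_categories()].
#' @param patients Character vector fixing the patient axis (patients with no
#'   mutations get all-zero rows).
#' @param category_map Classification-to-category table.
#' @return A `feature_matrix` of counts.
#' @export
build_low_res <- function(mutations, category, patients,
                          category_map = default_category_map()) {
  mutations <- .categorized(mutations, category_map)
  mutations <- mutations[mutations$category == category, , drop = FALSE]
  genes <- sort(unique(mutations$gene_symbol))
  values <- .count_matrix(mutations$patient_id, mutations$gene_symbol,
                          patients, genes)
  features <- data.frame(
    feature_id = if (length(genes)) paste0(genes, "|", category, "|gene") else character(),
    resolution = rep("LOW", length(genes)),
    category = rep(category, length(genes)),
    gene_symbol = genes,
    stringsAsFactors = FALSE
  )
  colnames(values) <- features$feature_id
  feature_matrix(values, features, patients)
}

#' Build medium-resolution (50-nucleotide segment) features
#'
#' For non-flank categories, the gene body (5'UTR through 3'UTR) is tiled into
#' consecutive 50-nucleotide segments anchored at its lowest genomic
#' coordinate; a mutation is assigned to the segment containing its start
#' coordinate, and one feature is emitted per (gene, segment) with at least
#' one mutation in the cohort. For the `FLANK` category the two features per
#' gene count mutations on the 5' and 3' flank sides. Mutations outside the
#' annotated gene body are assigned to the nearest terminal segment with a
#' warning.
#'
#' @inheritParams build_low_res
#' @param annotation A `gene_annotation` (see [make_annotation()]) supplying
#'   gene body bounds.
#' @param segment_length Segment width in nucleotides (default 50).
#' @return A `feature_matrix` of counts.
#' @export
build_medium_res <- function(mutations, annotation, category, patients,
                             segment_length = 50L,
                             category_map = default_category_map()) {
  mutations <- .categorized(mutations, category_map)
  mutations <- mutations[mutations$category == category, , drop = FALSE]
  if (nrow(mutations) == 0L) return(.empty_fm(patients))
  if (category == "FLANK") {
    side <- ifelse(mutations$variant_classification == "5'Flank", "5p", "3p")
    key <- paste0(mutations$gene_symbol, "|FLANK|", side)
    genes <- sort(unique(mutations$gene_symbol))
    keys <- if (length(genes)) {
      as.vector(t(outer(genes, c("5p", "3p"),
                        function(g, s) paste0(g, "|FLANK|", s))))
    } else {
      character()
    }
    values <- .count_matrix(mutations$patient_id, key, patients, keys)
    features <- data.frame(
      feature_id = keys,
      resolution = rep("MEDIUM", length(keys)),
      category = rep("FLANK", length(keys)),
      gene_symbol = rep(genes, each = 2L)[seq_along(keys)],
      flank_side = rep(c("5p", "3p"), times = length(genes)),
      stringsAsFactors = FALSE
    )
    colnames(values) <- keys
    return(feature_matrix(values, features, patients))
  }
  genes <- annotation$genes
  gi <- match(mutations$gene_symbol, genes$gene_symbol)
  if (anyNA(gi)) {
    stopf("mutated gene(s) missing from annotation: %s",
          paste(utils::head(unique(mutations$gene_symbol[is.na(gi)]), 5L),
                collapse = ", "))
  }
  offset <- mutations$start - genes$body_start[gi]
  body_len <- genes$body_end[gi] - genes$body_start[gi] + 1L
  n_seg <- ceiling(body_len / segment_length)
  seg <- floor(offset / segment_length)
  outside <- seg < 0L | seg >= n_seg
  if (any(outside)) {
    warnf("%d mutation(s) outside the annotated gene body; assigned to the nearest terminal segment",
          sum(outside))
    seg <- pmax(0L, pmin(seg, n_seg - 1L))
  }
  key <- paste0(mutations$gene_symbol, "|", category, "|seg", seg)
  keys <- sort(unique(key))
  values <- .count_matrix(mutations$patient_id, key, patients, keys)
  meta <- unique(data.frame(feature_id = key, gene_symbol = mutations$gene_symbol,
                            segment = seg, stringsAsFactors = FALSE))
  meta <- meta[match(keys, meta$feature_id), , drop = FALSE]
  features <- data.frame(
    feature_id = keys,
    resolution = rep("MEDIUM", length(keys)),
    category = rep(category, length(keys)),
    gene_symbol = meta$gene_symbol,
    segment = meta$segment,
    stringsAsFactors = FALSE
  )
  feature_matrix(values, features, patients)
}

#' Build high-resolution (exact mutation) binary features
#'
#' One binary feature per distinct mutation (position, classification,
#' polymorphism type and alleles all distinguish mutations) carried by at
#' least `min_carriers` patients in the cohort; mutations seen in a single
#' patient are discarded.
#'
#' @inheritParams build_low_res
#' @param min_carriers Minimum number of distinct carriers for a feature to be
#'   retained (default 2, i.e. singletons dropped).
#' @return A binary `feature_matrix`.
#' @export
build_high_res <- function(mutations, category, patients, min_carriers = 2L,
                           category_map = default_category_map()) {
  mutations <- .categorized(mutations, category_map)
  mutations <- mutations[mutations$category == category, , drop = FALSE]
  if (nrow(mutations) == 0L) return(.empty_fm(patients))
  id <- encode_feature_id(mutations)
  carrier <- unique(data.frame(patient_id = mutations$patient_id,
                               id = id,
                               gene_symbol = mutations$gene_symbol,
                               variant_type = mutations$variant_type,
                               stringsAsFactors = FALSE))
  counts <- table(carrier$id)
  kept <- names(counts)[counts >= min_carriers]
  carrier <- carrier[carrier$id %in% kept, , drop = FALSE]
  keys <- sort(kept)
  values <- .count_matrix(carrier$patient_id, carrier$id, patients, keys)
  meta <- unique(carrier[c("id", "gene_symbol", "variant_type")])
  meta <- meta[match(keys, meta$id), , drop = FALSE]
  features <- data.frame(
    feature_id = keys,
    resolution = rep("HIGH", length(keys)),
    category = rep(category, length(keys)),
    gene_symbol = meta$gene_symbol,
    mutation_id = keys,
    variant_type = meta$variant_type,
    stringsAsFactors = FALSE
  )
  feature_matrix(values, features, patients)
}

#' Build the six analysis datasets
#'
#' Builds, for each of the five mutation categories, the union of its low,
#' medium and high-resolution features, plus the all-features dataset that
#' concatenates the five.
#'
#' @inheritParams build_medium_res
#' @param min_carriers Singleton-discard threshold for high-resolution
#'   features.
#' @return Named list of six `feature_matrix` objects: the five categories
#'   plus `"ALL"`.
#' @export
build_datasets <- function(mutations, annotation, patients,
                           segment_length = 50L, min_carriers = 2L,
                           category_map = default_category_map()) {
  per_cat <- lapply(mutation_categories(), function(cat) {
    assemble_dataset(
      build_low_res(mutations, cat, patients, category_map),
      build_medium_res(mutations, annotation, cat, patients,
                       segment_length, category_map),
      build_high_res(mutations, cat, patients, min_carriers, category_map)
    )
  })
  names(per_cat) <- mutation_categories()
  c(per_cat, list(ALL = assemble_dataset(per_cat)))
}
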