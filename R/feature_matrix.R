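# Sparse patients x features container with per-feature metadata.

#' Construct a feature matrix
#'
#' A `feature_matrix` couples a sparse patients-by-features value matrix with
#' per-feature metadata: the resolution (`LOW` = whole-gene count, `MEDIUM` =
#' 50-nucleotide-segment count, `HIGH` = binary exact-mutation indicator), the
#' mutation category, the gene, and for medium/high features the segment index
#' or flank side / encoded mutation id and polymorphism type.
#'
#' @param values Matrix-like (coerced to sparse `dgCMatrix`), rows = patients,
#'   columns = features.
#' @param features Data frame with one row per column of `values`; must
#'   contain `feature_id`, `resolution`, `category`, `gene_symbol`; optional
#'   `segment`, `flank_side`, `mutation_id`, `variant_type`.
#' @param patients Character vector of patient ids (defaults to rownames).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, features, patients = rownames(values)) {
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  if (is.null(patients)) stopf("patient ids are required")
  if (nrow(features) != ncol(values)) {
    stopf("feature metadata has %d rows but the matrix has %d columns",
          nrow(features), ncol(values))
  }
  req <- c("feature_id", "resolution", "category", "gene_symbol")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols)) {
    stopf("feature metadata is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(features$feature_id)) stopf("duplicate feature ids")
  for (col in c("segment", "flank_side", "mutation_id", "variant_type")) {
    if (!col %in% names(features)) features[[col]] <- rep(NA, nrow(features))
  }
  rownames(values) <- patients
  colnames(values) <- features$feature_id
  rownames(features) <- NULL
  structure(list(values = values, features = features,
                 patients = as.character(patients)),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$features$category, x$features$resolution)
  if (length(tab)) print(tab)
  invisible(x)
}

#' Subset a feature matrix by feature
#'
#' @param fm A `feature_matrix`.
#' @param keep Logical or integer index over features.
#' @return A `feature_matrix` with the selected columns.
#' @export
subset_features <- function(fm, keep) {
  feature_matrix(fm$values[, keep, drop = FALSE],
                 fm$features[keep, , drop = FALSE], fm$patients)
}

#' Binarize a feature matrix
#'
#' Replaces every positive count with 1. High-resolution features are already
#' binary and are unchanged; the operation is idempotent.
#'
#' @param fm A `feature_matrix`.
#' @return A binary `feature_matrix` with identical metadata.
#' @export
binarize <- function(fm) {
  v <- fm$values
  v@x <- as.numeric(v@x > 0)
  feature_matrix(Matrix::drop0(v), fm$features, fm$patients)
}

#' Concatenate feature matrices column-wise
#'
#' Assembles a dataset from component matrices (e.g. the three resolutions of
#' one category, or the five single-category datasets into the all-features
#' dataset). All components must share the identical patient axis.
#'
#' @param ... `feature_matrix` objects, or a single list of them.
#' @return The concatenated `feature_matrix`.
#' @export
assemble_dataset <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "feature_matrix")) {
    parts <- parts[[1]]
  }
  parts <- Filter(function(p) !is.null(p), parts)
  if (!length(parts)) stopf("no feature matrices to assemble")
  pat <- parts[[1]]$patients
  for (p in parts) {
    if (!identical(p$patients, pat)) stopf("patient axes differ between components")
  }
  values <- do.call(cbind, lapply(parts, function(p) p$values))
  features <- do.call(rbind, lapply(parts, function(p) p$features))
  feature_matrix(values, features, pat)
}

# patient x key count matrix from parallel character vectors; duplicated
# (patient, key) pairs are summed. Guarantees the full patient axis.
.count_matrix <- function(patient, key, patients, keys = sort(unique(key))) {
  m <- Matrix::sparseMatrix(
    i = match(patient, patients),
    j = match(key, keys),
    x = rep(1, length(patient)),
    dims = c(length(patients), length(keys))
  )
  rownames(m) <- patients
  colnames(m) <- keys
  m
}
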