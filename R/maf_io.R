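# Readers and writers for MAF-style mutation tables and clinical tables,
# plus the cohort eligibility filter.

.maf_columns <- c(
  patient_id = "Tumor_Sample_Barcode",
  gene_symbol = "Hugo_Symbol",
  chrom = "Chromosome",
  start = "Start_Position",
  end = "End_Position",
  variant_classification = "Variant_Classification",
  variant_type = "Variant_Type",
  ref_allele = "Reference_Allele",
  tumor_allele1 = "Tumor_Seq_Allele1",
  tumor_allele2 = "Tumor_Seq_Allele2"
)

#' Normalize patient identifiers
#'
#' TCGA-style sample barcodes (`TCGA-XX-XXXX-...`) identify a patient by their
#' first 12 characters; other identifiers are kept verbatim (or matched with a
#' caller-supplied regular expression whose first capture group is the patient
#' id).
#'
#' @param x Character vector of sample identifiers.
#' @param pattern Optional regex with one capture group extracting the patient
#'   id; overrides the TCGA rule.
#' @return Character vector of patient identifiers.
#' @export
normalize_patient_id <- function(x, pattern = NULL) {
  x <- as.character(x)
  if (!is.null(pattern)) {
    return(sub(pattern, "\\1", x))
  }
  tcga <- grepl("^TCGA-", x)
  x[tcga] <- substr(x[tcga], 1L, 12L)
  x
}

#' Read a MAF-style somatic mutation table
#'
#' Reads a tab-delimited mutation annotation file (1-based inclusive
#' coordinates, TCGA column names) into the internal mutation record layout.
#' Unknown columns are ignored; rows whose coordinates cannot be parsed are
#' dropped with a warning naming their row indices.
#'
#' @param path Path to a tab-delimited MAF file.
#' @param column_map Named character vector mapping internal field names to
#'   file column names; defaults to the TCGA dialect.
#' @param id_pattern Passed to [normalize_patient_id()].
#' @return Data frame with columns `patient_id`, `sample_id`, `gene_symbol`,
#'   `chrom`, `start`, `end`, `variant_classification`, `variant_type`,
#'   `ref_allele`, `tumor_allele1`, `tumor_allele2`.
#' @export
read_maf <- function(path, column_map = .maf_columns, id_pattern = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           comment.char = "#")
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (nrow(raw) == 0L && length(missing_cols) == length(column_map)) {
    warnf("empty MAF file: %s", path)
    return(.empty_mutations())
  }
  if (length(missing_cols)) {
    stopf("MAF file %s is missing required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  out <- stats::setNames(raw[unname(column_map)], names(column_map))
  if (nrow(out) == 0L) {
    warnf("MAF file has no mutation rows: %s", path)
    return(.empty_mutations())
  }
  out$sample_id <- out$patient_id
  out$patient_id <- normalize_patient_id(out$patient_id, id_pattern)
  out$start <- suppressWarnings(as.integer(out$start))
  out$end <- suppressWarnings(as.integer(out$end))
  bad <- which(is.na(out$start) | is.na(out$end) | out$start > out$end)
  if (length(bad)) {
    warnf("dropping %d row(s) with unparseable coordinates: rows %s",
          length(bad), paste(utils::head(bad, 20L), collapse = ", "))
    out <- out[-bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out[c("patient_id", "sample_id", names(.maf_columns)[-1])]
}

.empty_mutations <- function() {
  data.frame(
    patient_id = character(), sample_id = character(),
    gene_symbol = character(), chrom = character(),
    start = integer(), end = integer(),
    variant_classification = character(), variant_type = character(),
    ref_allele = character(), tumor_allele1 = character(),
    tumor_allele2 = character(), stringsAsFactors = FALSE
  )
}

#' Write mutations in MAF layout
#'
#' @param mutations Mutation data frame (internal layout).
#' @param path Output path for the tab-delimited file.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path) {
  out <- mutations[names(.maf_columns)]
  out$patient_id <- if ("sample_id" %in% names(mutations)) {
    mutations$sample_id
  } else {
    mutations$patient_id
  }
  names(out) <- unname(.maf_columns)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' @param path Tab-delimited file with columns `patient_id`, `cancer_type`,
#'   `vital_status` (`alive`/`deceased`), `days_to_death`,
#'   `days_to_last_followup` (missing values empty or `NA`).
#' @return Data frame with those columns, days fields integer.
#' @export
read_clinical <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  req <- c("patient_id", "cancer_type", "vital_status",
           "days_to_death", "days_to_last_followup")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stopf("clinical file %s is missing required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  out <- raw[req]
  out$days_to_death <- suppressWarnings(as.integer(out$days_to_death))
  out$days_to_last_followup <- suppressWarnings(as.integer(out$days_to_last_followup))
  out
}

#' Write a clinical table
#'
#' @param clinical Clinical data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  cols <- c("patient_id", "cancer_type", "vital_status",
            "days_to_death", "days_to_last_followup")
  for (col in setdiff(cols, names(clinical))) clinical[[col]] <- NA
  utils::write.table(clinical[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict mutation and clinical tables to eligible patients
#'
#' Discards patients with missing genomic or clinical data (present in only
#' one of the two tables, or with no recorded cancer type) and patients with
#' multiple genomic samples. The filter is total and idempotent.
#'
#' @param mutations Mutation data frame (internal layout).
#' @param clinical Clinical data frame.
#' @return List with elements `mutations`, `clinical` (both restricted) and
#'   `exclusions`, a named integer vector counting patients dropped per
#'   reason (`no_genomic`, `no_clinical`, `multi_sample`, `no_cancer_type`).
#' @export
filter_patients <- function(mutations, clinical) {
  genomic_patients <- unique(mutations$patient_id)
  clinical_patients <- unique(clinical$patient_id)
  no_genomic <- setdiff(clinical_patients, genomic_patients)
  no_clinical <- setdiff(genomic_patients, clinical_patients)
  no_type <- clinical$patient_id[is.na(clinical$cancer_type) |
                                   clinical$cancer_type == ""]
  multi <- character()
  if ("sample_id" %in% names(mutations)) {
    n_samples <- tapply(mutations$sample_id, mutations$patient_id,
                        function(s) length(unique(s)))
    multi <- names(n_samples)[n_samples > 1L]
  }
  keep <- setdiff(intersect(genomic_patients, clinical_patients),
                  union(multi, no_type))
  list(
    mutations = mutations[mutations$patient_id %in% keep, , drop = FALSE],
    clinical = clinical[clinical$patient_id %in% keep, , drop = FALSE],
    exclusions = c(
      no_genomic = length(no_genomic),
      no_clinical = length(no_clinical),
      multi_sample = length(intersect(multi, clinical_patients)),
      no_cancer_type = length(unique(no_type))
    )
  )
}
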