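# Mutation category vocabulary and high-resolution feature identifiers.

#' The five mutation categories
#'
#' Every retained somatic mutation is sorted into exactly one of five
#' categories: amino-acid-altering exonic mutations (`NON_SILENT`) and four
#' kinds of silent mutations (`SYNONYMOUS` coding changes, `INTRON`, `UTR`,
#' and `FLANK` for the regions immediately up/downstream of a gene).
#'
#' @return Character vector of the five category names.
#' @export
#' @examples
#' mutation_categories()
mutation_categories <- function() {
  c("NON_SILENT", "SYNONYMOUS", "INTRON", "UTR", "FLANK")
}

#' Default mapping from MAF variant classifications to categories
#'
#' The mapping follows the TCGA MAF controlled vocabulary: protein-altering
#' exonic calls (missense, nonsense, nonstop, frameshift and in-frame indels,
#' translation start site, splice site) are `NON_SILENT`; `Silent` is
#' `SYNONYMOUS`; `Intron` and `Splice_Region` are `INTRON`; the two UTR and
#' two flank classifications map to `UTR` and `FLANK`. Classifications not in
#' the table (e.g. `RNA`, `IGR`) are excluded from all analyses. The table is
#' a plain named vector so alternative dialects can be supplied wherever a
#' `category_map` argument is accepted.
#'
#' @return Named character vector: names are variant classifications, values
#'   are categories.
#' @export
default_category_map <- function() {
  c(
    Missense_Mutation      = "NON_SILENT",
    Nonsense_Mutation      = "NON_SILENT",
    Nonstop_Mutation       = "NON_SILENT",
    Frame_Shift_Del        = "NON_SILENT",
    Frame_Shift_Ins        = "NON_SILENT",
    In_Frame_Del           = "NON_SILENT",
    In_Frame_Ins           = "NON_SILENT",
    Translation_Start_Site = "NON_SILENT",
    Splice_Site            = "NON_SILENT",
    Silent                 = "SYNONYMOUS",
    Intron                 = "INTRON",
    Splice_Region          = "INTRON",
    "3'UTR"                = "UTR",
    "5'UTR"                = "UTR",
    "3'Flank"              = "FLANK",
    "5'Flank"              = "FLANK"
  )
}

#' Sort variant classifications into the five mutation categories
#'
#' @param variant_classification Character vector of MAF variant
#'   classification strings.
#' @param category_map Named character vector mapping classification strings
#'   to categories; defaults to [default_category_map()].
#' @return Character vector of the same length with values in
#'   [mutation_categories()] or `"EXCLUDED"` for unmapped classifications.
#' @export
#' @examples
#' categorize(c("Silent", "Splice_Region", "Missense_Mutation", "RNA"))
categorize <- function(variant_classification,
                       category_map = default_category_map()) {
  out <- unname(category_map[as.character(variant_classification)])
  out[is.na(out)] <- "EXCLUDED"
  out
}

#' Encode a mutation as a high-resolution feature identifier
#'
#' A specific mutation is identified by the string
#' `"{start}-{end}-{chrom}-{classification}-{type}-{ref}-{allele1}-{allele2}"`,
#' with `-` standing for an empty allele, so that two different substitutions
#' at one position (say A>G and A>C) are distinct features.
#'
#' @param mutations Data frame with columns `start`, `end`, `chrom`,
#'   `variant_classification`, `variant_type`, `ref_allele`, `tumor_allele1`,
#'   `tumor_allele2` (as produced by [read_maf()] or [simulate_cohort()]).
#' @return Character vector of feature identifiers, one per row.
#' @seealso [decode_feature_id()]
#' @export
#' @examples
#' m <- data.frame(
#'   start = 140753336, end = 140753336, chrom = "chr7",
#'   variant_classification = "Missense_Mutation", variant_type = "SNP",
#'   ref_allele = "A", tumor_allele1 = "A", tumor_allele2 = "T"
#' )
#' encode_feature_id(m)
encode_feature_id <- function(mutations) {
  blank <- function(x) ifelse(is.na(x) | x == "", "-", as.character(x))
  paste(mutations$start, mutations$end, mutations$chrom,
        mutations$variant_classification, mutations$variant_type,
        blank(mutations$ref_allele), blank(mutations$tumor_allele1),
        blank(mutations$tumor_allele2),
        sep = "-")
}

#' Decode a high-resolution feature identifier
#'
#' Inverse of [encode_feature_id()]: `decode_feature_id(encode_feature_id(x))`
#' recovers the fields of `x`. An allele is either a base string or the
#' single character `-` (empty allele); since base strings never contain a
#' dash, the eight segments parse unambiguously.
#'
#' @param ids Character vector of feature identifiers.
#' @return Data frame with columns `start`, `end`, `chrom`,
#'   `variant_classification`, `variant_type`, `ref_allele`, `tumor_allele1`,
#'   `tumor_allele2`.
#' @export
decode_feature_id <- function(ids) {
  allele_re <- "([A-Za-z]+|-)"
  pattern <- paste0("^([0-9]+)-([0-9]+)-([^-]+)-([^-]+)-(SNP|DEL|INS)-",
                    allele_re, "-", allele_re, "-", allele_re, "$")
  rows <- lapply(seq_along(ids), function(i) {
    m <- regmatches(ids[i], regexec(pattern, ids[i]))[[1]]
    if (!length(m)) .diagnose_feature_id(ids[i])
    data.frame(
      start = as.integer(m[2]), end = as.integer(m[3]), chrom = m[4],
      variant_classification = m[5], variant_type = m[6],
      ref_allele = m[7], tumor_allele1 = m[8], tumor_allele2 = m[9],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# pinpoint which segment of a malformed feature id fails to parse
.diagnose_feature_id <- function(id) {
  p <- strsplit(id, "-", fixed = TRUE)[[1]]
  if (length(p) && is.na(suppressWarnings(as.integer(p[1])))) {
    stopf("malformed feature id '%s': bad start segment '%s'", id, p[1])
  }
  if (length(p) >= 2L && is.na(suppressWarnings(as.integer(p[2])))) {
    stopf("malformed feature id '%s': bad end segment '%s'", id, p[2])
  }
  if (length(p) >= 5L && !p[5] %in% c("SNP", "DEL", "INS")) {
    stopf("malformed feature id '%s': bad variant type segment '%s'", id, p[5])
  }
  stopf("malformed feature id '%s': expected 8 dash-separated segments (alleles may be '-')",
        id)
}
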