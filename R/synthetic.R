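# Synthetic cohort generator: gene annotations, MAF + clinical tables with
# planted cancer-type-specific mutation signatures, and proportional-hazards
# survival times. Every piece of planted truth is returned so downstream
# recovery can be tested.

#' Generate a synthetic gene annotation
#'
#' Each gene occupies its own chromosome and is laid out, in genomic order, as
#' 5' flank, 5'UTR, alternating exons and introns, 3'UTR and 3' flank. Exons
#' are split into a protein-altering part and a synonymous part so every
#' position maps to exactly one mutation category. The gene body (5'UTR
#' through 3'UTR) is always at least 150 nucleotides so 50-nucleotide
#' segmentation is non-degenerate.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed; the annotation is deterministic given the seed.
#' @param n_exons Exons per gene.
#' @param flank_length Length of each flanking region in nucleotides.
#' @return A `gene_annotation`: list with `genes` (gene_symbol, chrom,
#'   body_start, body_end) and `regions` (one row per category-homogeneous
#'   span: gene_symbol, chrom, region, category, start, end).
#' @export
make_annotation <- function(n_genes, seed = 1L, n_exons = 3L,
                            flank_length = 1000L) {
  stopifnot(n_genes >= 1L, n_exons >= 1L)
  local_seed(seed, {
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    all_regions <- vector("list", n_genes)
    gene_rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      chrom <- paste0("chr", g)
      origin <- sample.int(1e6L, 1L)
      utr5 <- sample(60:200, 1L)
      utr3 <- sample(60:200, 1L)
      exon_len <- sample(90:240, n_exons, replace = TRUE)
      intron_len <- if (n_exons > 1L) sample(200:800, n_exons - 1L, replace = TRUE) else integer()
      # ordered spans: label, length, category
      spans <- list(list("flank5", flank_length, "FLANK"),
                    list("utr5", utr5, "UTR"))
      for (e in seq_len(n_exons)) {
        ns_len <- ceiling(exon_len[e] * 0.7)
        spans <- c(spans, list(
          list(sprintf("exon%d_ns", e), ns_len, "NON_SILENT"),
          list(sprintf("exon%d_syn", e), exon_len[e] - ns_len, "SYNONYMOUS")
        ))
        if (e < n_exons) {
          spans <- c(spans, list(list(sprintf("intron%d", e), intron_len[e], "INTRON")))
        }
      }
      spans <- c(spans, list(list("utr3", utr3, "UTR"),
                             list("flank3", flank_length, "FLANK")))
      len <- vapply(spans, function(s) as.integer(s[[2]]), integer(1))
      start <- origin + c(0L, cumsum(len)[-length(len)])
      regions <- data.frame(
        gene_symbol = genes[g],
        chrom = chrom,
        region = vapply(spans, function(s) s[[1]], character(1)),
        category = vapply(spans, function(s) s[[3]], character(1)),
        start = start,
        end = start + len - 1L,
        stringsAsFactors = FALSE
      )
      body <- regions[!regions$category == "FLANK", ]
      gene_rows[[g]] <- data.frame(
        gene_symbol = genes[g], chrom = chrom,
        body_start = min(body$start), body_end = max(body$end),
        stringsAsFactors = FALSE
      )
      all_regions[[g]] <- regions
    }
    structure(list(genes = do.call(rbind, gene_rows),
                   regions = do.call(rbind, all_regions)),
              class = "gene_annotation")
  })
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes, %d regions\n",
              nrow(x$genes), nrow(x$regions)))
  invisible(x)
}

#' Specify a planted cancer-type signature signal
#'
#' A signal is either an exact recurrent mutation (`kind = "mutation"`: the
#' same position and alleles in every carrier, recoverable by a
#' high-resolution feature) or a gene-level burden (`kind = "gene"`: each
#' carrier receives a mutation of the category at a random position in the
#' gene, recoverable by a low-resolution feature). Each patient of the
#' signal's cancer type carries it independently with probability
#' `prevalence`.
#'
#' @param cancer_type Cancer type code the signal belongs to.
#' @param gene_symbol Gene carrying the signal.
#' @param category Mutation category of the signal.
#' @param prevalence Carrier probability in `[0, 1]`.
#' @param kind `"mutation"` or `"gene"`.
#' @return A `signature_signal` list.
#' @export
signature_signal <- function(cancer_type, gene_symbol, category,
                             prevalence, kind = c("mutation", "gene")) {
  kind <- match.arg(kind)
  stopifnot(prevalence >= 0, prevalence <= 1,
            category %in% mutation_categories())
  structure(list(cancer_type = cancer_type, gene_symbol = gene_symbol,
                 category = category, prevalence = prevalence, kind = kind),
            class = "signature_signal")
}

#' Cohort simulation configuration
#'
#' Defaults emulate the gross shape of real tumor cohorts: strong category
#' imbalance with non-silent mutations most frequent (non-silent >> intron >
#' UTR > synonymous > flank) and a polymorphism mixture dominated by SNPs
#' with a minority of small deletions and insertions.
#'
#' @param patients_per_type Named integer vector: patients per cancer type.
#' @param background_rates Named Poisson means (mutations per patient) per
#'   category.
#' @param mixture_weights Named SNP/DEL/INS probabilities (sum to 1).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(patients_per_type,
                          background_rates = c(NON_SILENT = 10, INTRON = 5,
                                               UTR = 3, SYNONYMOUS = 2,
                                               FLANK = 1),
                          mixture_weights = c(SNP = 0.90, DEL = 0.07,
                                              INS = 0.03),
                          seed = 1L) {
  stopifnot(all(background_rates >= 0),
            abs(sum(mixture_weights) - 1) < 1e-8,
            all(mutation_categories() %in% names(background_rates)),
            all(c("SNP", "DEL", "INS") %in% names(mixture_weights)))
  structure(list(patients_per_type = patients_per_type,
                 background_rates = background_rates,
                 mixture_weights = mixture_weights,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.bases <- c("A", "C", "G", "T")

# draw n mutations of one category, vectorized; gene=NULL draws cohort-wide
.simulate_mutations <- function(patient_ids, category, regions, weights,
                                gene = NULL) {
  n <- length(patient_ids)
  pool <- regions[regions$category == category, , drop = FALSE]
  if (!is.null(gene)) pool <- pool[pool$gene_symbol == gene, , drop = FALSE]
  if (!nrow(pool)) {
    stopf("no region of category %s available%s", category,
          if (is.null(gene)) "" else paste0(" in gene ", gene))
  }
  if (n == 0L) return(.empty_mutations())
  lens <- pool$end - pool$start + 1L
  idx <- sample.int(nrow(pool), n, replace = TRUE, prob = lens)
  pos <- pool$start[idx] + as.integer(floor(stats::runif(n) * lens[idx]))
  vt <- if (category == "SYNONYMOUS") {
    rep("SNP", n)  # synonymous changes are substitutions by definition
  } else {
    sample(c("SNP", "DEL", "INS"), n, replace = TRUE,
           prob = weights[c("SNP", "DEL", "INS")])
  }
  vc <- character(n)
  is_snp <- vt == "SNP"; is_del <- vt == "DEL"; is_ins <- vt == "INS"
  if (category == "NON_SILENT") {
    vc[is_snp] <- sample(c("Missense_Mutation", "Nonsense_Mutation", "Splice_Site"),
                         sum(is_snp), replace = TRUE, prob = c(0.9, 0.08, 0.02))
    vc[is_del] <- sample(c("Frame_Shift_Del", "In_Frame_Del"), sum(is_del),
                         replace = TRUE, prob = c(0.8, 0.2))
    vc[is_ins] <- sample(c("Frame_Shift_Ins", "In_Frame_Ins"), sum(is_ins),
                         replace = TRUE, prob = c(0.8, 0.2))
  } else if (category == "SYNONYMOUS") {
    vc[] <- "Silent"
  } else if (category == "INTRON") {
    vc <- sample(c("Intron", "Splice_Region"), n, replace = TRUE,
                 prob = c(0.9, 0.1))
  } else if (category == "UTR") {
    vc <- ifelse(startsWith(pool$region[idx], "utr5"), "5'UTR", "3'UTR")
  } else {
    vc <- ifelse(startsWith(pool$region[idx], "flank5"), "5'Flank", "3'Flank")
  }
  ref <- a1 <- a2 <- character(n)
  snp_ref <- sample(.bases, sum(is_snp), replace = TRUE)
  ref[is_snp] <- snp_ref
  a1[is_snp] <- snp_ref
  # alternate allele: rotate away from the reference base
  a2[is_snp] <- .bases[(match(snp_ref, .bases) - 1L +
                          sample.int(3L, sum(is_snp), replace = TRUE)) %% 4L + 1L]
  del_ref <- sample(.bases, sum(is_del), replace = TRUE)
  ref[is_del] <- del_ref; a1[is_del] <- del_ref; a2[is_del] <- "-"
  ref[is_ins] <- "-"; a1[is_ins] <- "-"
  a2[is_ins] <- sample(.bases, sum(is_ins), replace = TRUE)
  data.frame(
    patient_id = patient_ids, sample_id = patient_ids,
    gene_symbol = pool$gene_symbol[idx], chrom = pool$chrom[idx],
    start = pos, end = pos,
    variant_classification = vc, variant_type = vt,
    ref_allele = ref, tumor_allele1 = a1, tumor_allele2 = a2,
    stringsAsFactors = FALSE
  )
}

#' Simulate a synthetic cohort with planted signatures
#'
#' Each patient receives, per category, `Poisson(background_rate)` background
#' mutations at length-weighted uniform positions within regions of that
#' category, plus each planted signal of their cancer type independently with
#' its prevalence. Exact-mutation signals place an identical mutation in every
#' carrier; gene-level signals place a fresh random mutation of the signal's
#' category inside the signal's gene.
#'
#' @param annotation A `gene_annotation`.
#' @param signatures List of [signature_signal()] objects (possibly empty).
#' @param config A [cohort_config()].
#' @return List with `mutations` (MAF-layout data frame), `clinical`
#'   (patient_id, cancer_type; survival fields `NA` until
#'   [simulate_survival()]), `truth` (patient_id, cancer_type, signal_id,
#'   carrier) and `signals` (signal_id, cancer_type, gene_symbol, category,
#'   kind, prevalence, feature_id for exact-mutation signals).
#' @export
simulate_cohort <- function(annotation, signatures = list(), config) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(config, "cohort_config"))
  regions <- annotation$regions
  for (s in signatures) {
    hit <- regions$gene_symbol == s$gene_symbol & regions$category == s$category
    if (!any(hit)) {
      stopf("signal in gene %s has no region of category %s",
            s$gene_symbol, s$category)
    }
  }
  local_seed(config$seed, {
    # freeze the exact-mutation signals' identities first
    signal_rows <- vector("list", length(signatures))
    planted_template <- vector("list", length(signatures))
    for (k in seq_along(signatures)) {
      s <- signatures[[k]]
      sid <- sprintf("sig%02d_%s_%s_%s", k, s$cancer_type, s$gene_symbol,
                     s$category)
      fid <- NA_character_
      if (s$kind == "mutation") {
        tmpl <- .simulate_mutations("template", s$category, regions,
                                    config$mixture_weights, s$gene_symbol)
        planted_template[[k]] <- tmpl
        fid <- encode_feature_id(tmpl)
      }
      signal_rows[[k]] <- data.frame(
        signal_id = sid, cancer_type = s$cancer_type,
        gene_symbol = s$gene_symbol, category = s$category, kind = s$kind,
        prevalence = s$prevalence, feature_id = fid, stringsAsFactors = FALSE
      )
    }
    signals <- if (length(signal_rows)) do.call(rbind, signal_rows) else
      data.frame(signal_id = character(), cancer_type = character(),
                 gene_symbol = character(), category = character(),
                 kind = character(), prevalence = numeric(),
                 feature_id = character(), stringsAsFactors = FALSE)

    types <- names(config$patients_per_type)
    mut_parts <- list()
    truth_parts <- list()
    clin_parts <- list()
    for (ty in types) {
      n <- config$patients_per_type[[ty]]
      pids <- sprintf("%s_%03d", ty, seq_len(n))
      clin_parts[[ty]] <- data.frame(
        patient_id = pids, cancer_type = ty, vital_status = NA_character_,
        days_to_death = NA_integer_, days_to_last_followup = NA_integer_,
        stringsAsFactors = FALSE
      )
      for (cat in mutation_categories()) {
        counts <- stats::rpois(n, config$background_rates[[cat]])
        mut_parts[[length(mut_parts) + 1L]] <-
          .simulate_mutations(rep(pids, counts), cat, regions,
                              config$mixture_weights)
      }
      for (k in which(signals$cancer_type == ty)) {
        carrier <- stats::runif(n) < signals$prevalence[k]
        truth_parts[[length(truth_parts) + 1L]] <- data.frame(
          patient_id = pids, cancer_type = ty,
          signal_id = signals$signal_id[k], carrier = carrier,
          stringsAsFactors = FALSE
        )
        if (any(carrier)) {
          if (signals$kind[k] == "mutation") {
            tmpl <- planted_template[[k]]
            rows <- tmpl[rep(1L, sum(carrier)), , drop = FALSE]
            rows$patient_id <- pids[carrier]
            rows$sample_id <- pids[carrier]
            mut_parts[[length(mut_parts) + 1L]] <- rows
          } else {
            mut_parts[[length(mut_parts) + 1L]] <-
              .simulate_mutations(pids[carrier], signals$category[k], regions,
                                  config$mixture_weights,
                                  signals$gene_symbol[k])
          }
        }
      }
    }
    mutations <- if (length(mut_parts)) do.call(rbind, mut_parts) else .empty_mutations()
    rownames(mutations) <- NULL
    truth <- if (length(truth_parts)) do.call(rbind, truth_parts) else
      data.frame(patient_id = character(), cancer_type = character(),
                 signal_id = character(), carrier = logical(),
                 stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    clinical <- do.call(rbind, clin_parts)
    rownames(clinical) <- NULL
    list(mutations = mutations, clinical = clinical, truth = truth,
         signals = signals)
  })
}

#' Survival simulation specification
#'
#' Event times follow a proportional-hazards model with exponential baseline:
#' `T_i ~ Exponential(h0 * exp(sum_j beta_j x_ij))`, administratively censored
#' at `horizon` days.
#'
#' @param baseline_hazard Baseline hazard `h0` per day (> 0).
#' @param log_hr Named numeric vector of per-feature log hazard ratios
#'   (names are feature ids of the supplied feature matrix).
#' @param horizon Administrative censoring horizon in days (> 0).
#' @param seed Integer seed.
#' @return A `survival_spec` list.
#' @export
survival_spec <- function(baseline_hazard, log_hr = numeric(), horizon,
                          seed = 1L) {
  stopifnot(baseline_hazard > 0, horizon > 0)
  structure(list(baseline_hazard = baseline_hazard, log_hr = log_hr,
                 horizon = horizon, seed = as.integer(seed)),
            class = "survival_spec")
}

#' Simulate survival outcomes for a cohort
#'
#' Fills the clinical table's vital status and day fields from the
#' proportional-hazards model of a [survival_spec()]: deceased patients get
#' `days_to_death`, administratively censored patients are alive with
#' `days_to_last_followup` equal to the horizon.
#'
#' @param clinical Clinical data frame (one row per patient).
#' @param features A `feature_matrix` (or patients x features matrix) whose
#'   columns include the names of `spec$log_hr`; values are used as-is in the
#'   linear predictor.
#' @param spec A [survival_spec()].
#' @return The clinical data frame with survival fields populated.
#' @export
simulate_survival <- function(clinical, features, spec) {
  stopifnot(inherits(spec, "survival_spec"))
  X <- if (inherits(features, "feature_matrix")) features$values else features
  lp <- rep(0, nrow(clinical))
  if (length(spec$log_hr)) {
    missing_feat <- setdiff(names(spec$log_hr), colnames(X))
    if (length(missing_feat)) {
      stopf("log_hr names absent from feature matrix: %s",
            paste(missing_feat, collapse = ", "))
    }
    lp <- as.numeric(X[match(clinical$patient_id, rownames(X)),
                       names(spec$log_hr), drop = FALSE] %*% spec$log_hr)
  }
  local_seed(spec$seed, {
    t_event <- stats::rexp(nrow(clinical),
                           rate = spec$baseline_hazard * exp(lp))
    days <- pmax(1L, as.integer(ceiling(t_event)))
    event <- days <= spec$horizon
    clinical$vital_status <- ifelse(event, "deceased", "alive")
    clinical$days_to_death <- ifelse(event, days, NA_integer_)
    clinical$days_to_last_followup <- ifelse(event, NA_integer_,
                                             as.integer(spec$horizon))
    clinical
  })
}
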