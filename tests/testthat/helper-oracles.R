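# Independent brute-force oracles and small fixture builders. The oracles are
# deliberately written as plain nested loops / textbook formulas, sharing no
# code with the implementation they check.

# -- fixtures ----------------------------------------------------------------

# random mutation table drawn directly (not via the simulator) over an
# annotation, for feature-engineering equivalence tests
random_mutations <- function(annotation, patients, n, seed) {
  regions <- annotation$regions
  set.seed(seed)
  idx <- sample.int(nrow(regions), n, replace = TRUE)
  pos <- regions$start[idx] +
    sapply(idx, function(i) sample.int(regions$end[i] - regions$start[i] + 1L, 1L)) - 1L
  vc <- vapply(seq_len(n), function(k) {
    switch(regions$category[idx[k]],
           NON_SILENT = sample(c("Missense_Mutation", "Frame_Shift_Del",
                                 "Splice_Site"), 1L),
           SYNONYMOUS = "Silent",
           INTRON = sample(c("Intron", "Splice_Region"), 1L),
           UTR = if (grepl("5", regions$region[idx[k]])) "5'UTR" else "3'UTR",
           FLANK = if (grepl("5", regions$region[idx[k]])) "5'Flank" else "3'Flank")
  }, character(1))
  vt <- ifelse(vc == "Silent", "SNP",
               sample(c("SNP", "DEL", "INS"), n, replace = TRUE))
  ref <- ifelse(vt == "INS", "-", sample(c("A", "C", "G", "T"), n, replace = TRUE))
  alt <- ifelse(vt == "DEL", "-", sample(c("A", "C", "G", "T"), n, replace = TRUE))
  data.frame(
    patient_id = sample(patients, n, replace = TRUE),
    sample_id = NA_character_,
    gene_symbol = regions$gene_symbol[idx], chrom = regions$chrom[idx],
    start = pos, end = pos,
    variant_classification = vc, variant_type = vt,
    ref_allele = ref, tumor_allele1 = ref, tumor_allele2 = alt,
    stringsAsFactors = FALSE
  )
}

# tiny planted-signal cohort used across classification tests
planted_cohort <- function(seed, n_per_type = 60L, types = c("TA", "TB"),
                           prevalence = 0.5, background = 2) {
  ann <- make_annotation(6L, seed = seed)
  rates <- setNames(rep(background, 5L), mutation_categories())
  sigs <- list(
    signature_signal(types[1], "GENE001", "NON_SILENT", prevalence, "mutation"),
    signature_signal(types[2], "GENE002", "INTRON", prevalence, "gene")
  )
  cfg <- cohort_config(setNames(rep(n_per_type, length(types)), types),
                       background_rates = rates, seed = seed + 1L)
  sim <- simulate_cohort(ann, sigs, cfg)
  pats <- sort(unique(sim$clinical$patient_id))
  list(ann = ann, sim = sim, patients = pats,
       datasets = build_datasets(sim$mutations, ann, pats))
}

# -- oracles -----------------------------------------------------------------

# per-(patient, gene) mutation count of one category, nested loops
oracle_low_counts <- function(mutations, category, patients) {
  cats <- categorize(mutations$variant_classification)
  rows <- mutations[cats == category, , drop = FALSE]
  genes <- sort(unique(rows$gene_symbol))
  out <- matrix(0, length(patients), length(genes),
                dimnames = list(patients, genes))
  for (k in seq_len(nrow(rows))) {
    out[rows$patient_id[k], rows$gene_symbol[k]] <-
      out[rows$patient_id[k], rows$gene_symbol[k]] + 1
  }
  out
}

# carrier matrix per distinct encoded mutation (>= min_carriers patients)
oracle_high_counts <- function(mutations, category, patients,
                               min_carriers = 2L) {
  cats <- categorize(mutations$variant_classification)
  rows <- mutations[cats == category, , drop = FALSE]
  ids <- encode_feature_id(rows)
  keep_ids <- character()
  for (id in sort(unique(ids))) {
    if (length(unique(rows$patient_id[ids == id])) >= min_carriers) {
      keep_ids <- c(keep_ids, id)
    }
  }
  out <- matrix(0, length(patients), length(keep_ids),
                dimnames = list(patients, keep_ids))
  for (k in seq_len(nrow(rows))) {
    if (ids[k] %in% keep_ids) out[rows$patient_id[k], ids[k]] <- 1
  }
  out
}

# per-(patient, gene, segment) counts of one non-flank category
oracle_medium_counts <- function(mutations, annotation, category, patients,
                                 seg_len = 50L) {
  cats <- categorize(mutations$variant_classification)
  rows <- mutations[cats == category, , drop = FALSE]
  key <- character(nrow(rows))
  for (k in seq_len(nrow(rows))) {
    g <- annotation$genes[annotation$genes$gene_symbol == rows$gene_symbol[k], ]
    key[k] <- sprintf("%s|%s|seg%d", rows$gene_symbol[k], category,
                      (rows$start[k] - g$body_start) %/% seg_len)
  }
  keys <- sort(unique(key))
  out <- matrix(0, length(patients), length(keys),
                dimnames = list(patients, keys))
  for (k in seq_len(nrow(rows))) {
    out[rows$patient_id[k], key[k]] <- out[rows$patient_id[k], key[k]] + 1
  }
  out
}

# mean pairwise Jaccard by explicit double loop over patients
oracle_mean_jaccard <- function(A, B) {
  total <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      fa <- colnames(A)[A[i, ] > 0]
      fb <- colnames(B)[B[j, ] > 0]
      u <- length(union(fa, fb))
      total <- total + if (u == 0) 0 else length(intersect(fa, fb)) / u
    }
  }
  total / (nrow(A) * nrow(B))
}

# cumulative/dynamic AUC by exhaustive pair enumeration
oracle_auc <- function(risk, event, time, t) {
  num <- 0; den <- 0
  for (i in seq_along(risk)) {
    if (!(event[i] == 1 && time[i] <= t)) next
    for (j in seq_along(risk)) {
      if (!(time[j] > t)) next
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Spearman rho as Pearson correlation of ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Pearson r from the covariance formula
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# the feature ids that encode one planted signal at the three resolutions:
# the exact mutation id, its 50-nt segment, and the whole-gene count
planted_aliases <- function(signal, annotation, seg_len = 50L) {
  ids <- c(sprintf("%s|%s|gene", signal$gene_symbol, signal$category))
  if (!is.na(signal$feature_id)) {
    dec <- decode_feature_id(signal$feature_id)
    g <- annotation$genes[annotation$genes$gene_symbol == signal$gene_symbol, ]
    seg <- (dec$start - g$body_start) %/% seg_len
    ids <- c(signal$feature_id, ids,
             sprintf("%s|%s|seg%d", signal$gene_symbol, signal$category, seg))
  }
  ids
}

# hand-made two-gene annotation with round coordinates
toy_annotation <- function() {
  genes <- data.frame(
    gene_symbol = c("GA", "GB"), chrom = c("chr1", "chr2"),
    body_start = c(1001L, 5001L), body_end = c(1400L, 5250L),
    stringsAsFactors = FALSE
  )
  regions <- data.frame(
    gene_symbol = c("GA", "GA", "GA", "GA", "GA", "GB", "GB", "GB"),
    chrom = c(rep("chr1", 5), rep("chr2", 3)),
    region = c("flank5", "utr5", "intron1", "utr3", "flank3",
               "utr5", "intron1", "utr3"),
    category = c("FLANK", "UTR", "INTRON", "UTR", "FLANK",
                 "UTR", "INTRON", "UTR"),
    start = c(1L, 1001L, 1101L, 1301L, 1401L, 5001L, 5101L, 5201L),
    end = c(1000L, 1100L, 1300L, 1400L, 2400L, 5100L, 5200L, 5250L),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, regions = regions), class = "gene_annotation")
}

# minimal mutation row in the internal layout
mut_row <- function(patient, gene, chrom, pos, vc, vt = "SNP",
                    ref = "A", a1 = "A", a2 = "T", end = pos) {
  data.frame(patient_id = patient, sample_id = patient, gene_symbol = gene,
             chrom = chrom, start = pos, end = end,
             variant_classification = vc, variant_type = vt,
             ref_allele = ref, tumor_allele1 = a1, tumor_allele2 = a2,
             stringsAsFactors = FALSE)
}
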