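test_that("low-resolution features are per-gene category counts", {
  muts <- rbind(
    mut_row("p1", "GA", "chr1", 1150, "Intron"),
    mut_row("p1", "GA", "chr1", 1160, "Intron"),
    mut_row("p1", "GA", "chr1", 1170, "Intron"),
    mut_row("p2", "GA", "chr1", 1150, "Intron"),
    mut_row("p1", "GA", "chr1", 1050, "5'UTR"),
    mut_row("p2", "GB", "chr2", 5150, "Intron")
  )
  low <- build_low_res(muts, "INTRON", c("p1", "p2", "p3"))
  expect_equal(as.numeric(low$values["p1", "GA|INTRON|gene"]), 3)
  expect_equal(as.numeric(low$values["p2", "GA|INTRON|gene"]), 1)
  expect_equal(as.numeric(low$values["p2", "GB|INTRON|gene"]), 1)
  expect_equal(as.numeric(low$values["p3", ]), c(0, 0))
  # the UTR mutation is not counted in the intron dataset
  expect_equal(sum(low$values), 5)
})

test_that("two-patient toy cohort yields the expected intron and UTR features", {
  # two patients with marked mutations in one gene, as in a feature-extraction
  # walkthrough: counts per gene, per 50-nt segment, and binary exact matches
  ann <- toy_annotation()
  muts <- rbind(
    mut_row("p1", "GA", "chr1", 1110, "Intron"),        # segment 2
    mut_row("p1", "GA", "chr1", 1130, "Intron"),        # segment 2
    mut_row("p2", "GA", "chr1", 1210, "Intron"),        # segment 4
    mut_row("p1", "GA", "chr1", 1020, "5'UTR"),
    mut_row("p2", "GA", "chr1", 1020, "5'UTR"),         # same exact mutation
    mut_row("p2", "GA", "chr1", 1350, "3'UTR")
  )
  pats <- c("p1", "p2")
  low_i <- build_low_res(muts, "INTRON", pats)
  expect_equal(as.numeric(low_i$values[, "GA|INTRON|gene"]), c(2, 1))
  low_u <- build_low_res(muts, "UTR", pats)
  expect_equal(as.numeric(low_u$values[, "GA|UTR|gene"]), c(1, 2))
  med_i <- build_medium_res(muts, ann, "INTRON", pats)
  expect_equal(as.numeric(med_i$values[, "GA|INTRON|seg2"]), c(2, 0))
  expect_equal(as.numeric(med_i$values[, "GA|INTRON|seg4"]), c(0, 1))
  high_u <- build_high_res(muts, "UTR", pats)
  # only the shared 5'UTR substitution has two carriers
  expect_equal(ncol(high_u$values), 1L)
  expect_equal(as.numeric(high_u$values), c(1, 1))
})

test_that("segment indices anchor at the gene body start", {
  ann <- toy_annotation()  # GA body starts at 1001
  muts <- rbind(
    mut_row("p1", "GA", "chr1", 1073, "Intron"),  # floor(72 / 50) = 1
    mut_row("p1", "GA", "chr1", 1001, "5'UTR"),   # gene start -> segment 0
    mut_row("p2", "GA", "chr1", 1001, "5'UTR")
  )
  med <- build_medium_res(muts, ann, "INTRON", c("p1", "p2"))
  expect_equal(med$features$segment, 1)
  med_u <- build_medium_res(muts, ann, "UTR", c("p1", "p2"))
  expect_equal(med_u$features$segment, 0)
})

test_that("flank features count the two sides separately", {
  muts <- rbind(
    mut_row("p1", "GA", "chr1", 500, "5'Flank"),
    mut_row("p1", "GA", "chr1", 1500, "3'Flank"),
    mut_row("p2", "GA", "chr1", 1600, "3'Flank")
  )
  med <- build_medium_res(muts, toy_annotation(), "FLANK", c("p1", "p2"))
  expect_setequal(med$features$feature_id,
                  c("GA|FLANK|5p", "GA|FLANK|3p"))
  expect_equal(as.numeric(med$values[, "GA|FLANK|5p"]), c(1, 0))
  expect_equal(as.numeric(med$values[, "GA|FLANK|3p"]), c(1, 1))
})

test_that("mutations outside the gene body fall into terminal segments", {
  ann <- toy_annotation()
  muts <- mut_row("p1", "GA", "chr1", 990, "Intron")  # before body start
  expect_warning(med <- build_medium_res(muts, ann, "INTRON", "p1"),
                 "terminal segment")
  expect_equal(med$features$segment, 0)
})

test_that("high-resolution features drop singletons and split by allele", {
  muts <- rbind(
    mut_row("p1", "GA", "chr1", 1150, "Intron", a2 = "G"),
    mut_row("p2", "GA", "chr1", 1150, "Intron", a2 = "G"),
    mut_row("p3", "GA", "chr1", 1150, "Intron", a2 = "C"),  # other allele
    mut_row("p4", "GA", "chr1", 1150, "Intron", a2 = "C"),
    mut_row("p5", "GA", "chr1", 1200, "Intron")             # singleton
  )
  pats <- sprintf("p%d", 1:5)
  high <- build_high_res(muts, "INTRON", pats)
  # the A>G and A>C substitutions at 1150 are distinct; the singleton is gone
  expect_equal(ncol(high$values), 2L)
  expect_true(all(Matrix::colSums(high$values) == 2))
  expect_true(all(high$values@x %in% c(0, 1)))
})

test_that("feature matrices equal the brute-force counting oracle", {
  for (trial in 1:100) {
    ann <- make_annotation(sample(2:5, 1), seed = trial)
    pats <- sprintf("p%02d", seq_len(sample(5:50, 1)))
    muts <- random_mutations(ann, pats, sample(30:120, 1), seed = trial + 500)
    for (cat in c("NON_SILENT", "INTRON", "UTR")) {
      low <- build_low_res(muts, cat, pats)
      expect_equal(as.matrix(low$values),
                   oracle_low_counts(muts, cat, pats)[
                     , low$features$gene_symbol, drop = FALSE],
                   ignore_attr = TRUE)
      high <- build_high_res(muts, cat, pats)
      expect_equal(as.matrix(high$values),
                   oracle_high_counts(muts, cat, pats),
                   ignore_attr = TRUE)
      med <- build_medium_res(muts, ann, cat, pats)
      expect_equal(as.matrix(med$values),
                   oracle_medium_counts(muts, ann, cat, pats),
                   ignore_attr = TRUE)
      # conservation: segment counts sum to the gene count
      for (g in unique(low$features$gene_symbol)) {
        seg_cols <- med$features$gene_symbol == g
        expect_equal(Matrix::rowSums(med$values[, seg_cols, drop = FALSE]),
                     low$values[, paste0(g, "|", cat, "|gene")],
                     ignore_attr = TRUE)
      }
      # singleton filter
      if (ncol(high$values)) {
        expect_gte(min(Matrix::colSums(high$values)), 2)
      }
    }
  }
})

test_that("datasets assemble as disjoint unions with aligned patients", {
  fix <- planted_cohort(seed = 3, n_per_type = 20)
  ds <- fix$datasets
  expect_equal(ncol(ds$ALL$values),
               sum(sapply(ds[mutation_categories()],
                          function(d) ncol(d$values))))
  for (cat in mutation_categories()) {
    expect_equal(ds[[cat]]$patients, ds$ALL$patients)
    expect_true(all(ds[[cat]]$features$category == cat))
  }
  sub <- subset_features(ds$INTRON, ds$INTRON$features$resolution == "HIGH")
  expect_true(all(sub$features$feature_id %in% ds$INTRON$features$feature_id))
  mismatched <- feature_matrix(ds$ALL$values[1:5, ], ds$ALL$features,
                               ds$ALL$patients[1:5])
  expect_error(assemble_dataset(ds$ALL, mismatched), "patient axes")
})

test_that("binarization clamps counts and is idempotent", {
  fix <- planted_cohort(seed = 5, n_per_type = 15)
  fm <- fix$datasets$ALL
  b <- binarize(fm)
  expect_true(all(b$values@x %in% c(0, 1)))
  expect_equal(as.matrix(b$values), (as.matrix(fm$values) > 0) * 1,
               ignore_attr = TRUE)
  expect_equal(binarize(b)$values, b$values)
  # high-resolution features unchanged
  hi <- fm$features$resolution == "HIGH"
  expect_equal(b$values[, hi], fm$values[, hi])
})
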