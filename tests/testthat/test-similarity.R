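test_that("Jaccard similarity obeys its definition and bounds", {
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5, tolerance = 1e-12)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_equal(jaccard(character(), character()), 0)  # both empty
  set.seed(6)
  for (i in 1:50) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_gte(jaccard(a, b), 0)
    expect_lte(jaccard(a, b), 1)
    if (length(a)) expect_equal(jaccard(a, a), 1)
  }
})

test_that("the Jaccard protocol equals the brute-force double loop", {
  fm <- feature_matrix(
    Matrix::Matrix(matrix(rbinom(100, 1, 0.4), 10, 10), sparse = TRUE),
    data.frame(feature_id = sprintf("f%02d", 1:10), resolution = "HIGH",
               category = "NON_SILENT", gene_symbol = "G1"),
    sprintf("p%02d", 1:10)
  )
  clinical <- data.frame(patient_id = sprintf("p%02d", 1:10),
                         cancer_type = rep(c("A", "B"), each = 5))
  # sample size = cohort size: every repetition is the exhaustive computation
  jp <- jaccard_pair_protocol(fm, clinical, "A", "B", sample_size = 5,
                              n_reps = 3, seed = 1)
  A <- as.matrix(fm$values[1:5, ])
  B <- as.matrix(fm$values[6:10, ])
  expect_equal(jp$J, oracle_mean_jaccard(A, B), tolerance = 1e-12)
  expect_equal(unique(round(jp$per_rep, 12)), round(jp$J, 12))
  # identical profiles across the two groups give similarity 1
  clone <- feature_matrix(fm$values[c(1:5, 1:5), ], fm$features,
                          sprintf("q%02d", 1:10))
  jp2 <- jaccard_pair_protocol(clone, data.frame(
    patient_id = sprintf("q%02d", 1:10),
    cancer_type = rep(c("A", "B"), each = 5)), "A", "B",
    sample_size = 5, n_reps = 1, seed = 1)
  expect_gte(jp2$J, oracle_mean_jaccard(A, A) - 1e-12)
})

test_that("cohorts get lowered sample sizes with a message", {
  fm <- feature_matrix(
    Matrix::Matrix(diag(6), sparse = TRUE),
    data.frame(feature_id = sprintf("f%d", 1:6), resolution = "HIGH",
               category = "UTR", gene_symbol = "G"),
    sprintf("p%d", 1:6)
  )
  clinical <- data.frame(patient_id = sprintf("p%d", 1:6),
                         cancer_type = rep(c("A", "B"), each = 3))
  expect_message(jp <- jaccard_pair_protocol(fm, clinical, "A", "B",
                                             sample_size = 100, n_reps = 2,
                                             seed = 1),
                 "lowered")
  expect_equal(jp$sample_size, 3)
  expect_equal(jp$J, 0)  # disjoint feature sets
})

test_that("misclassification follows the confusion-count formula", {
  fix <- planted_cohort(seed = 23, n_per_type = 40)
  mp <- misclassification_protocol(fix$datasets$ALL, fix$sim$clinical,
                                   "TA", "TB", sample_size = 30, n_reps = 4,
                                   seed = 2)
  # M recomputed by hand from the stored confusion counts
  hand <- (mp$confusion[, "AB"] + mp$confusion[, "BA"]) /
    (mp$confusion[, "AA"] + mp$confusion[, "AB"] +
       mp$confusion[, "BA"] + mp$confusion[, "BB"])
  expect_equal(mp$per_rep, hand, tolerance = 1e-12)
  expect_equal(mp$M, mean(hand), tolerance = 1e-12)
  # every repetition's confusion counts sum to the test-set size
  # (30 patients per type, 0.3 held out: 9 + 9 = 18)
  expect_true(all(rowSums(mp$confusion) == 18))
})

test_that("separable cohorts have low M; label noise drives M to one half", {
  # fully separable: disjoint planted signatures, no background
  ann <- make_annotation(4, seed = 2)
  rates <- setNames(rep(0, 5), mutation_categories())
  sigs <- list(signature_signal("A", "GENE001", "NON_SILENT", 1, "mutation"),
               signature_signal("B", "GENE002", "INTRON", 1, "mutation"))
  cfg <- cohort_config(c(A = 30, B = 30), background_rates = rates, seed = 5)
  sim <- simulate_cohort(ann, sigs, cfg)
  pats <- sort(unique(sim$clinical$patient_id))
  ds <- build_datasets(sim$mutations, ann, pats)
  mp <- misclassification_protocol(ds$ALL, sim$clinical, "A", "B",
                                   sample_size = 30, n_reps = 3, seed = 3)
  expect_lt(mp$M, 0.05)

  # shuffled cancer-type labels: misclassification approaches one half
  shuffled <- sim$clinical
  set.seed(9)
  shuffled$cancer_type <- sample(shuffled$cancer_type)
  mp2 <- misclassification_protocol(ds$ALL, shuffled, "A", "B",
                                    sample_size = 25, n_reps = 6, seed = 3)
  expect_lt(abs(mp2$M - 0.5), 0.2)
})

test_that("similarity-misclassification correlation matches the rank oracle", {
  pairs <- data.frame(J = c(0.1, 0.3, 0.2, 0.5, 0.4),
                      M = c(0.05, 0.30, 0.12, 0.45, 0.38))
  out <- similarity_vs_misclassification(pairs)
  expect_equal(out$rho, oracle_spearman(pairs$J, pairs$M), tolerance = 1e-12)
  expect_equal(out$n_pairs, 5)
  expect_error(similarity_vs_misclassification(pairs[1:2, ]), "at least 3")
  # constant J: undefined, reported missing
  const <- data.frame(J = rep(0.2, 4), M = c(0.1, 0.2, 0.3, 0.4))
  expect_true(is.na(similarity_vs_misclassification(const)$rho))
})

test_that("F1 improvement and burden increase follow their formulas", {
  expect_equal(f1_improvement(0.5, 0.4), 25, tolerance = 1e-12)
  expect_equal(f1_improvement(0.3, 0.4), -25, tolerance = 1e-12)
  expect_equal(f1_improvement(0.4, 0.4), 0)
  expect_true(is.na(f1_improvement(0.5, 0)))

  # every patient doubles: 100%
  expect_equal(mb_increase(c(p1 = 4, p2 = 10), c(p1 = 2, p2 = 5))$mb_increase,
               100, tolerance = 1e-12)
  # (+50%, +150%) averages to 100%
  expect_equal(mb_increase(c(p1 = 3, p2 = 5), c(p1 = 2, p2 = 2))$mb_increase,
               100, tolerance = 1e-12)
  # no silent mutations anywhere: 0
  expect_equal(mb_increase(c(p1 = 2, p2 = 5), c(p1 = 2, p2 = 5))$mb_increase,
               0)
  # zero non-silent burden excluded and counted
  out <- mb_increase(c(p1 = 3, p2 = 4), c(p1 = 0, p2 = 2))
  expect_equal(out$mb_increase, 100)
  expect_equal(out$n_excluded, 1)
  all_zero <- mb_increase(c(p1 = 3), c(p1 = 0))
  expect_true(is.na(all_zero$mb_increase))
})

test_that("per-patient burdens count retained mutations by category", {
  muts <- rbind(
    mut_row("p1", "GA", "chr1", 1150, "Intron"),
    mut_row("p1", "GA", "chr1", 1050, "Missense_Mutation"),
    mut_row("p1", "GA", "chr1", 1060, "RNA"),     # excluded classification
    mut_row("p2", "GB", "chr2", 5150, "Silent")
  )
  b_all <- mutational_burden(muts, c("p1", "p2", "p3"))
  expect_equal(unname(b_all), c(2, 1, 0))
  b_ns <- mutational_burden(muts, c("p1", "p2", "p3"), "NON_SILENT")
  expect_equal(unname(b_ns), c(1, 0, 0))
})

test_that("improvement-burden correlation agrees with the covariance oracle", {
  rec <- data.frame(f1_improvement = c(5, 12, 8, 30, 22, 18),
                    mb_increase = c(40, 90, 55, 200, 160, 120))
  out <- improvement_burden_correlation(rec)
  expect_equal(out$r, oracle_pearson(rec$f1_improvement, rec$mb_increase),
               tolerance = 1e-12)
  expect_equal(out$r_squared, out$r^2, tolerance = 1e-12)
  # exactly linear: r = 1
  lin <- data.frame(f1_improvement = 1:5, mb_increase = 2 * (1:5) + 3)
  expect_equal(improvement_burden_correlation(lin)$r, 1, tolerance = 1e-12)
  expect_error(improvement_burden_correlation(lin[1:2, ]), "at least 3")
})
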