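test_that("gene rankings keep the best feature rank per gene", {
  imp <- data.frame(feature_id = c("f1", "f2", "f3"),
                    importance = c(0.5, 0.3, 0.2))
  gr <- derive_gene_ranking(imp, c(f1 = "A", f2 = "B", f3 = "A"))
  expect_equal(gr$gene_symbol, c("A", "B"))
  expect_equal(gr$rank, c(0L, 1L))

  # all-zero importances yield an empty ranking
  zero <- data.frame(feature_id = c("f1", "f2"), importance = c(0, 0))
  expect_equal(nrow(derive_gene_ranking(zero, c(f1 = "A", f2 = "B"))), 0L)

  # one feature per gene: gene order equals feature order
  imp3 <- data.frame(feature_id = c("a", "b", "c"),
                     importance = c(3, 2, 1))
  gr3 <- derive_gene_ranking(imp3, c(a = "X", b = "Y", c = "Z"))
  expect_equal(gr3$gene_symbol, c("X", "Y", "Z"))
  expect_equal(gr3$rank, 0:2)

  expect_error(derive_gene_ranking(imp3, c(a = "X", b = "Y")), "not mapped")
})

test_that("top-k category enrichment is calibrated on random rankings", {
  feats <- data.frame(
    feature_id = sprintf("f%03d", 1:200),
    resolution = "LOW",
    category = rep(mutation_categories(), each = 40),
    gene_symbol = sprintf("G%03d", 1:200),
    variant_type = NA
  )
  # uniform random rankings: enrichment of every category should approach 1
  rankings <- lapply(1:60, function(i) {
    set.seed(i)
    data.frame(feature_id = sample(feats$feature_id),
               importance = seq(200, 1) / 200)
  })
  dist <- topk_type_distribution(rankings, feats, k = 10)
  expect_equal(dist$dataset_fraction, rep(0.2, 5))
  expect_true(all(abs(dist$enrichment - 1) < 0.3))
  expect_equal(sum(dist$topk_fraction), 1, tolerance = 1e-12)

  # a ranking whose top-k is entirely non-silent leaves silent fractions at 0
  ordered <- list(data.frame(feature_id = feats$feature_id,
                             importance = seq(200, 1) / 200))
  d2 <- topk_type_distribution(ordered, feats, k = 10)
  expect_equal(d2$topk_fraction[d2$category == "NON_SILENT"], 1)
  expect_equal(sum(d2$topk_fraction[d2$category != "NON_SILENT"]), 0)
})

test_that("planted silent signals enrich their category in the top ranks", {
  ann <- make_annotation(6, seed = 2)
  rates <- setNames(rep(2, 5), mutation_categories())
  sigs <- list(signature_signal("TA", "GENE001", "SYNONYMOUS", 0.6, "mutation"))
  cfg <- cohort_config(c(TA = 60, TB = 60), background_rates = rates,
                       seed = 20)
  sim <- simulate_cohort(ann, sigs, cfg)
  pats <- sort(unique(sim$clinical$patient_id))
  ds <- build_datasets(sim$mutations, ann, pats)
  labels <- make_ova_labels(sim$clinical, "TA", min_cohort = 10)
  res <- train_ova(ds$ALL, labels, split_scheme(n_repeats = 5, seed = 3))
  # the planted synonymous substitution (at one of its three resolutions;
  # the boosted trees split credit among the correlated aliases) tops the
  # ranking and its (rare) category is over-represented in the top 10
  aliases <- planted_aliases(sim$signals[1, ], ann)
  expect_true(res$importance$feature_id[1] %in% aliases)
  dist <- topk_type_distribution(list(res$importance), ds$ALL$features, k = 10)
  expect_gt(dist$enrichment[dist$category == "SYNONYMOUS"], 1)
})

test_that("polymorphism enrichment uses high-resolution features only", {
  feats <- data.frame(
    feature_id = c(sprintf("h%02d", 1:20), "low1"),
    resolution = c(rep("HIGH", 20), "LOW"),
    category = "NON_SILENT",
    gene_symbol = "G1",
    variant_type = c(rep("SNP", 18), "DEL", "INS", NA)
  )
  # top-k composition identical to the dataset: enrichment 1 for SNP
  rk <- data.frame(feature_id = feats$feature_id,
                   importance = c(seq(21, 2) / 21, 1 / 21))
  pe <- polymorphism_enrichment(list(rk), feats, k = 20)
  expect_equal(pe$enrichment[pe$variant_type == "SNP"], 1, tolerance = 1e-12)

  # no high-resolution features in the top-k: reported missing
  rk2 <- data.frame(feature_id = c("low1", sprintf("h%02d", 1:20)),
                    importance = c(1, rep(0, 20)))
  pe2 <- polymorphism_enrichment(list(rk2), feats, k = 5)
  expect_true(all(is.na(pe2$enrichment)))
  expect_true(all(pe2$n_models == 0))
})

test_that("cross-model rank correlations recover known structure", {
  gr <- function(genes) data.frame(gene_symbol = genes,
                                   rank = seq_along(genes) - 1L)
  genes <- sprintf("G%02d", 1:20)
  rankings <- list(CT1 = list(
    m1 = gr(genes),
    m2 = gr(genes),          # identical -> rho 1
    m3 = gr(rev(genes))      # reversed  -> rho -1
  ))
  cm <- cross_model_rank_correlation(rankings)
  expect_equal(cm$rho["m1", "m2"], 1)
  expect_equal(cm$rho["m1", "m3"], -1)
  expect_equal(cm$rho["m2", "m3"], -1)
  expect_true(isSymmetric(cm$rho))

  # independent random rankings: mean rho near 0 over 20 cancer types
  rand <- lapply(1:20, function(i) {
    set.seed(100 + i)
    list(m1 = gr(sample(genes)), m2 = gr(sample(genes)))
  })
  names(rand) <- sprintf("CT%02d", 1:20)
  cm2 <- cross_model_rank_correlation(rand)
  expect_lt(abs(cm2$rho["m1", "m2"]), 0.3)

  # small intersections are skipped
  tiny <- list(CT1 = list(m1 = gr(c("A", "B")), m2 = gr(c("A", "C"))))
  expect_message(cm3 <- cross_model_rank_correlation(tiny), "skipped")
  expect_true(is.na(cm3$rho["m1", "m2"]))
})

test_that("rank correlations agree with the rank-then-Pearson oracle", {
  set.seed(8)
  for (i in 1:20) {
    x <- sample(50, 12)
    y <- sample(50, 12)
    st <- silentmut:::spearman_stat(x, y)
    expect_equal(st$rho, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("top-gene membership counts types and respects bounds", {
  lists <- list(
    CT1 = list(NS = c("TP53", "MUC4"), SYN = c("MUC4")),
    CT2 = list(NS = c("TP53"), SYN = c("MUC4", "KRAS")),
    CT3 = list(NS = c("TP53", "EGFR"), SYN = character())
  )
  mem <- top_gene_membership(lists)
  expect_equal(mem["TP53", "NS"], 3L)
  expect_equal(mem["MUC4", "SYN"], 2L)
  expect_equal(mem["MUC4", "NS"], 1L)
  expect_equal(mem["EGFR", "SYN"], 0L)
  expect_true(all(mem <= length(lists)))
  # column sums equal the total collapsed list lengths
  expect_equal(unname(colSums(mem)),
               c(sum(lengths(lapply(lists, `[[`, "NS"))),
                 sum(lengths(lapply(lists, `[[`, "SYN")))))
})

test_that("top gene lists collapse the top features in order without padding", {
  imp <- data.frame(feature_id = sprintf("f%d", 1:12),
                    importance = seq(12, 1))
  map <- setNames(rep(c("A", "B", "C"), each = 4), imp$feature_id)
  tg <- top_genes(imp, map, k = 10)
  expect_equal(tg, c("A", "B", "C"))  # fewer than 10 genes, no padding
})

test_that("mutation-count correlation behaves as a rank statistic", {
  gr <- data.frame(gene_symbol = sprintf("G%02d", 1:15), rank = 0:14)
  # counts aligned with importance order: best-ranked gene has most mutations
  counts <- setNames(seq(150, 10, length.out = 15), gr$gene_symbol)
  out <- mutation_count_rank_correlation(list(CT1 = gr), counts)
  expect_equal(out$per_type$rho, 1)
  # invariant to monotone transforms of the counts
  out_log <- mutation_count_rank_correlation(list(CT1 = gr), log(counts))
  expect_equal(out_log$per_type$rho, out$per_type$rho)
  # random counts: |rho| small on average
  set.seed(5)
  rhos <- replicate(30, {
    mutation_count_rank_correlation(
      list(CT1 = gr), setNames(sample(1000, 15), gr$gene_symbol))$mean_rho
  })
  expect_lt(abs(mean(rhos)), 0.2)
  # constant counts: undefined, reported missing
  const <- mutation_count_rank_correlation(
    list(CT1 = gr), setNames(rep(5, 15), gr$gene_symbol))
  expect_true(is.na(const$per_type$rho))
})
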