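test_that("generators are pure functions of parameters and seed", {
  a <- make_expression(n_genes = 30, n_samples = 12, seed = 5)
  b <- make_expression(n_genes = 30, n_samples = 12, seed = 5)
  expect_identical(a, b)
  c_ <- make_expression(n_genes = 30, n_samples = 12, seed = 6)
  expect_false(identical(a$matrix, c_$matrix))

  m1 <- make_toy_model(seed = 3)
  m2 <- make_toy_model(seed = 3)
  expect_identical(m1, m2)

  s1 <- make_survival(rep(1:2, 10), seed = 4)
  expect_identical(s1, make_survival(rep(1:2, 10), seed = 4))

  maf1 <- make_maf(setNames(rep(c("a", "b"), 20), sprintf("s%02d", 1:40)), seed = 7)
  maf2 <- make_maf(setNames(rep(c("a", "b"), 20), sprintf("s%02d", 1:40)), seed = 7)
  expect_identical(maf1, maf2)
})

test_that("expression generator plants the advertised block structure", {
  ex <- make_expression(n_genes = 40, n_samples = 20, r = 2, separation = 4,
                        noise = "none", seed = 8)
  X <- unclass(ex$matrix)
  tr <- ex$truth
  # in-block means dominate out-of-block means
  b1 <- names(tr$gene_block)[tr$gene_block == 1]
  s1 <- names(tr$labels)[tr$labels == 1]
  s2 <- names(tr$labels)[tr$labels == 2]
  expect_gt(mean(X[b1, s1]), 5 * mean(X[b1, s2]))
  expect_equal(expr_scale(ex$matrix), "normalized")
  expect_equal(expr_scale(make_expression(n_genes = 10, n_samples = 8,
                                          noise = "poisson", seed = 1)$matrix),
               "raw_counts")
})

test_that("toy model overlap interpolates between disjoint and shared pools", {
  disjoint <- make_toy_model(n_metabolites = 8, genes_per_met = 4, overlap = 0,
                             seed = 9)
  sets <- lapply(disjoint$model$reactions, `[[`, "genes")
  expect_equal(length(unique(unlist(sets))), 8 * 4) # fully private
  expect_true(all(lengths(sets) == 4))
  g <- build_bipartite_graph(disjoint$model)
  expect_true(all(igraph::degree(g, igraph::V(g)[!igraph::V(g)$type]) == 4))

  shared <- make_toy_model(n_metabolites = 8, genes_per_met = 4, overlap = 1,
                           seed = 10)
  pool <- shared$truth$shared_pool
  expect_true(all(unlist(lapply(shared$model$reactions, `[[`, "genes")) %in% pool))
})

test_that("planted DE scores shift only the planted neighborhoods", {
  tm <- make_toy_model(n_metabolites = 10, genes_per_met = 4, overlap = 0, seed = 11)
  planted <- tm$model$metabolites[1:2]
  de <- make_de_scores(tm$model, planted_mets = planted, effect = 3, seed = 12)
  truth <- attr(de, "truth")
  expect_length(truth$planted_genes, 8)
  planted_p <- de$p_value[de$gene %in% truth$planted_genes]
  other_p <- de$p_value[!de$gene %in% truth$planted_genes]
  expect_lt(median(planted_p), 0.01)
  expect_gt(median(other_p), 0.2)
  expect_true(all(de$log2FC[de$gene %in% truth$planted_genes] > 0))
  # pure null table
  de0 <- make_de_scores(tm$model, planted_mets = character(0), seed = 13)
  expect_length(attr(de0, "truth")$planted_genes, 0)
})

test_that("survival generator respects hazard ratio and censoring fraction", {
  labels <- rep(1:2, each = 250)
  surv <- make_survival(labels, hazard_ratio = 2, censor_frac = 0, seed = 14)
  expect_true(all(surv$event == 1))
  # group 2 events come systematically earlier
  expect_lt(median(surv$time[surv$group == 2]), median(surv$time[surv$group == 1]))
  surv2 <- make_survival(labels, hazard_ratio = 2, censor_frac = 0.2, seed = 15)
  expect_equal(mean(surv2$event == 0), 0.2, tolerance = 0.06)
  lr <- logrank_test(surv)
  expect_lt(lr$p, 0.001)
})

test_that("clinical generator hits the target Cramer's V", {
  labels <- rep(1:2, each = 250)
  v1 <- make_clinical(labels, target_v = 1, seed = 16)
  expect_equal(cramers_v(table(labels, v1)), 1)
  expect_equal(length(unique(v1)), 2) # deterministic category per subtype
  v0 <- make_clinical(labels, target_v = 0, seed = 17)
  expect_lt(cramers_v(table(labels, v0)), 0.15)
  vm <- vapply(1:20, function(s) {
    cramers_v(table(labels, make_clinical(labels, target_v = 0.6, seed = s)))
  }, numeric(1))
  expect_equal(median(vm), 0.6, tolerance = 0.07)
})

test_that("MAF generator plants differential genes and exclusive pairs", {
  labels <- setNames(rep(c("g1", "g2"), each = 100), sprintf("P%03d", 1:200))
  maf <- make_maf(labels,
                  planted_genes = data.frame(gene = "MUTD1",
                                             freq_group1 = 0.9, freq_group2 = 0.3),
                  exclusive_pairs = list(c("EXA", "EXB")), seed = 18)
  freq <- mutation_frequency(maf, names(labels)[labels == "g1"])
  expect_equal(freq$frequency[freq$gene == "MUTD1"], 0.9, tolerance = 0.1)
  # exclusive pair: never the same sample
  a <- unique(maf$sample[maf$gene == "EXA"])
  b <- unique(maf$sample[maf$gene == "EXB"])
  expect_length(intersect(a, b), 0)
  # silent rows exist and are excluded from the non-synonymous subset
  expect_true(any(!maf$nonsynonymous))
})

test_that("truth objects round-trip through JSON", {
  tm <- make_toy_model(n_metabolites = 5, genes_per_met = 3, seed = 19)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(tm$truth, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_metabolites, tm$truth$n_metabolites)
  expect_equal(back$shared_pool, tm$truth$shared_pool)
  expect_equal(back$overlap, tm$truth$overlap)
})
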