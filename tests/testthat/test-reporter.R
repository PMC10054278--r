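test_that("p-to-z conversion matches the standard normal quantile", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.025), qnorm(0.975), tolerance = 1e-10)
  expect_equal(p_to_z(0.025), 1.95996, tolerance = 1e-4)
  # clamping keeps the extremes finite
  expect_equal(p_to_z(0), qnorm(1e-15, lower.tail = FALSE))
  expect_true(is.finite(p_to_z(1)))
  expect_error(p_to_z(1.2), "\\[0, 1\\]")
  expect_error(p_to_z(-0.1), "\\[0, 1\\]")
})

test_that("neighborhood aggregation uses the 1/sqrt(k) prefactor over scored genes", {
  g <- build_bipartite_graph(toy_model())
  scores <- data.frame(gene = c("A", "B", "Z"), z = c(1, 1, 99))
  agg <- aggregate_metabolite_z(g, scores, "m2[c]")
  expect_equal(agg$k, 2L)
  expect_equal(agg$z_raw, sqrt(2))
  # single scored neighbor: prefactor cancels
  one <- aggregate_metabolite_z(g, data.frame(gene = "B", z = 1.7), "m3[m]")
  expect_equal(one$z_raw, 1.7)
  expect_equal(one$k, 1L)
  # no scored neighbors -> skipped
  none <- aggregate_metabolite_z(g, data.frame(gene = "Q", z = 1), "m1[c]")
  expect_true(none$skipped)
})

test_that("exhaustive background matches a brute-force enumeration to 1e-12", {
  set.seed(101)
  pool <- rnorm(5)
  bc <- background_correct(1.3, 2, pool, mode = "exhaustive")
  ref <- brute_background(pool, 2)
  expect_equal(bc$mu_k, ref$mu, tolerance = 1e-12)
  expect_equal(bc$sigma_k, ref$sigma, tolerance = 1e-12)
  expect_equal(bc$z_corrected, (1.3 - ref$mu) / ref$sigma, tolerance = 1e-12)
  expect_true(bc$exhaustive)
  expect_equal(bc$n_sets_used, choose(5, 2))
})

test_that("auto mode enumerates exhaustively when C(N,k) <= n_sets", {
  pool <- rnorm(10)
  bc <- background_correct(0, 3, pool, n_sets = 1000, seed = 1)
  expect_true(bc$exhaustive) # C(10,3) = 120 <= 1000
  bc2 <- background_correct(0, 3, pool, n_sets = 50, seed = 1)
  expect_false(bc2$exhaustive)
})

test_that("a z_raw equal to the background mean standardizes to zero", {
  pool <- c(0.1, 0.5, -0.3, 1.2, 0.7)
  ref <- brute_background(pool, 2)
  bc <- background_correct(ref$mu, 2, pool, mode = "exhaustive")
  expect_equal(bc$z_corrected, 0, tolerance = 1e-12)
})

test_that("constant score pools are flagged, not scored", {
  bc <- background_correct(1, 2, rep(0.5, 6))
  expect_equal(bc$error, "constant_pool")
  expect_true(is.na(bc$z_corrected))
})

test_that("sampling path is deterministic under a fixed seed", {
  pool <- rnorm(30)
  a <- background_correct(1, 3, pool, n_sets = 2000, seed = 9, mode = "sampling")
  b <- background_correct(1, 3, pool, n_sets = 2000, seed = 9, mode = "sampling")
  expect_identical(a, b)
})

test_that("prefactor choice cancels exactly after background correction", {
  set.seed(102)
  for (i in 1:10) {
    pool <- rnorm(sample(6:12, 1))
    k <- sample(1:3, 1)
    z_raw_sqrt <- sum(pool[1:k]) / sqrt(k)
    z_raw_k <- sum(pool[1:k]) / k
    a <- background_correct(z_raw_sqrt, k, pool, prefactor = "inv_sqrt_k",
                            mode = "exhaustive")
    b <- background_correct(z_raw_k, k, pool, prefactor = "inv_k",
                            mode = "exhaustive")
    expect_equal(a$z_corrected, b$z_corrected, tolerance = 1e-12)
  }
})

test_that("planted dysregulated neighborhoods rank first and pass the filters", {
  tm <- make_toy_model(n_metabolites = 15, genes_per_met = 3, overlap = 0, seed = 1)
  g <- build_bipartite_graph(tm$model)
  planted <- tm$model$metabolites[1]
  hits <- vapply(1:30, function(s) {
    de <- make_de_scores(tm$model, planted_mets = planted, effect = 3, seed = s)
    rep_ <- reporter_metabolites(g, de, "all", seed = s)
    nrow(rep_) > 0 && rep_$metabolite[1] == planted
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null gene scores yield no consistently significant metabolite", {
  tm <- make_toy_model(n_metabolites = 12, genes_per_met = 3, overlap = 0, seed = 2)
  g <- build_bipartite_graph(tm$model)
  de <- make_de_scores(tm$model, planted_mets = character(0), seed = 3)
  de$p_value <- 0.5
  de$adj_p <- 0.5
  rep_ <- reporter_metabolites(g, de, "all", seed = 4)
  expect_equal(nrow(rep_), 0)
})

test_that("min_k excludes small neighborhoods regardless of signal", {
  model <- metabolic_model(list(
    list(id = "R1", genes = c("A", "B"), metabolites = "m1[c]"),
    list(id = "R2", genes = c("C", "D", "E", "F"), metabolites = "m2[c]"),
    list(id = "R3", genes = c("G", "H", "I", "J"), metabolites = "m3[c]")
  ))
  g <- build_bipartite_graph(model)
  de <- data.frame(gene = LETTERS[1:10],
                   log2FC = 1,
                   p_value = c(1e-8, 1e-8, rep(0.5, 8)))
  rep_ <- reporter_metabolites(g, de, "all", min_k = 3, seed = 5)
  expect_false("m1[c]" %in% rep_$metabolite) # extreme but k = 2
  all_tab <- attr(rep_, "all_metabolites")
  expect_equal(all_tab$k[all_tab$metabolite == "m1[c]"], 2L)
})

test_that("directional modes restrict both scoring and background to one sign", {
  model <- metabolic_model(list(
    list(id = "R1", genes = c("A", "B", "C"), metabolites = "m1[c]"),
    list(id = "R2", genes = c("D", "E", "F"), metabolites = "m2[c]"),
    list(id = "R3", genes = c("G", "H", "I"), metabolites = "m3[c]"),
    list(id = "R4", genes = c("J", "K", "L"), metabolites = "m4[c]")
  ))
  g <- build_bipartite_graph(model)
  de <- data.frame(gene = LETTERS[1:12],
                   log2FC = c(2, 2, 2, -2, -2, -2, 1, 1, 1, -1, -1, -1),
                   p_value = c(0.001, 0.002, 0.003, 0.5, 0.6, 0.7,
                               0.3, 0.4, 0.5, 0.3, 0.4, 0.5))
  up <- reporter_metabolites(g, de, "up", min_k = 3, seed = 6)
  all_up <- attr(up, "all_metabolites")
  # m1 and m3 carry upregulated neighborhoods; m2/m4 have none and are skipped
  expect_setequal(all_up$metabolite, c("m1[c]", "m3[c]"))
  expect_setequal(attr(up, "skipped"), c("m2[c]", "m4[c]"))
  expect_equal(all_up$metabolite[1], "m1[c]") # the significant block ranks first
  down <- reporter_metabolites(g, de, "down", min_k = 3, seed = 6)
  expect_setequal(attr(down, "all_metabolites")$metabolite, c("m2[c]", "m4[c]"))
})

test_that("reporter output is byte-identical under a fixed seed", {
  tm <- make_toy_model(n_metabolites = 10, genes_per_met = 4, overlap = 0.4, seed = 7)
  g <- build_bipartite_graph(tm$model)
  de <- make_de_scores(tm$model, planted_mets = tm$model$metabolites[1:2], seed = 8)
  a <- reporter_metabolites(g, de, "all", seed = 99, n_sets = 5000)
  b <- reporter_metabolites(g, de, "all", seed = 99, n_sets = 5000)
  expect_identical(a, b)
})
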