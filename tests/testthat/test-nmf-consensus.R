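test_that("KL-NMF drives an exact rank-1 matrix to zero divergence", {
  X <- outer(c(2, 1), c(1, 2))
  dimnames(X) <- list(c("g1", "g2"), c("s1", "s2"))
  fit <- nmf_fit(X, 1, "brunet_kl", max_iter = 2000, tol = 0, seed = 1)
  expect_lt(tail(fit$objective, 1), 1e-6)
  expect_true(all(fit$W >= 0), all(fit$H >= 0))
})

test_that("multiplicative updates are monotone for KL and Frobenius objectives", {
  set.seed(10)
  X <- matrix(rpois(30 * 20, 8), 30, 20,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  for (m in c("brunet_kl", "lee_frobenius")) {
    fit <- nmf_fit(X, 3, m, max_iter = 300, tol = 0, seed = 2)
    expect_true(all(diff(fit$objective) <= 1e-9), info = m)
  }
})

test_that("exact low-rank inputs are reconstructed by every variant", {
  set.seed(4)
  W <- matrix(runif(40 * 2, 0.5, 2), 40, 2)
  H <- matrix(runif(2 * 25, 0.5, 2), 2, 25)
  X <- W %*% H
  dimnames(X) <- list(paste0("g", 1:40), paste0("s", 1:25))
  for (m in c("brunet_kl", "lee_frobenius", "offset")) {
    fit <- nmf_fit(X, 2, m, max_iter = 4000, tol = 0, seed = 5)
    expect_true(nmf_reconstruction_error(fit, X) < 1e-3, info = m)
  }
})

test_that("nmf_fit validates inputs", {
  X <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_error(nmf_fit(X, 2), "out of range")
  Xn <- X; Xn[1] <- -1
  expect_error(nmf_fit(Xn, 1), "negative")
})

test_that("labels come from the dominant meta-profile with first-row ties", {
  fit <- structure(list(H = matrix(c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8), 2, 3,
                                   dimnames = list(NULL, c("s1", "s2", "s3")))),
                   class = "nmf_fit")
  expect_equal(assign_labels(fit), c(s1 = 1L, s2 = 1L, s3 = 2L))
})

test_that("planted two-block data is recovered by a single NMF run", {
  ex <- make_expression(n_genes = 80, n_samples = 40, r = 2, separation = 4,
                        noise = "none", seed = 21)
  fit <- nmf_fit(ex$matrix, 2, "brunet_kl", max_iter = 500, tol = 1e-9, seed = 22)
  expect_lt(nmf_reconstruction_error(fit, ex$matrix), 0.05)
  expect_equal(adjusted_rand_index(assign_labels(fit), ex$truth$labels), 1)
})

test_that("consensus on noiseless two-block data is perfectly stable", {
  ex <- make_expression(n_genes = 60, n_samples = 30, r = 2, separation = 4,
                        noise = "none", seed = 31)
  cc <- suppressWarnings(
    consensus_cluster(ex$matrix, 2, "brunet_kl", runs = 12,
                      seed = 32, max_iter = 300, tol = 1e-8))
  off <- cc$C[upper.tri(cc$C)]
  expect_true(all(off %in% c(0, 1)))
  expect_equal(adjusted_rand_index(cc$labels, ex$truth$labels), 1)
  expect_equal(cc$cophenetic, 1)
  expect_equal(cc$dispersion, 1)
  expect_equal(cc$silhouette, 1)
})

test_that("consensus matrix is symmetric with unit diagonal and [0,1] entries", {
  ex <- make_expression(n_genes = 50, n_samples = 24, r = 2, separation = 2,
                        noise = "nb", seed = 41)
  X <- normalize_counts(ex$matrix)
  cc <- suppressWarnings(
    consensus_cluster(X, 2, "lee_frobenius", runs = 10, seed = 42,
                      max_iter = 200, tol = 1e-6))
  expect_equal(cc$C, t(cc$C))
  expect_true(all(cc$C >= 0 & cc$C <= 1))
  sampled <- diag(cc$cosampled) > 0
  expect_true(all(diag(cc$C)[sampled] == 1))
})

test_that("cophenetic coefficient matches a hand-built 4-sample dendrogram", {
  C <- matrix(c(1, .9, .2, .1,
                .9, 1, .3, .2,
                .2, .3, 1, .8,
                .1, .2, .8, 1), 4, 4)
  res <- list(C = C)
  # average linkage merges {1,2}@.1, {3,4}@.2, then all@(.8+.9+.7+.8)/4 = .8
  d_hand <- c(.1, .8, .9, .7, .8, .2)       # pairs 12,13,14,23,24,34
  coph_hand <- c(.1, .8, .8, .8, .8, .2)
  expect_equal(cophenetic_coefficient(res), cor(d_hand, coph_hand))
  # degenerate: all distances equal
  expect_warning(v <- cophenetic_coefficient(list(C = matrix(0.5, 3, 3))),
                 "undefined")
  expect_true(is.na(v))
})

test_that("dispersion follows its closed form", {
  expect_equal(dispersion(list(C = matrix(c(1, 0, 0, 1), 2, 2))), 1)
  expect_equal(dispersion(list(C = matrix(0.5, 3, 3))), 0)
  expect_equal(dispersion(list(C = matrix(c(1, .5, .5, 1), 2, 2))), 0.5)
})

test_that("silhouette matches a brute-force oracle and flags single clusters", {
  C <- matrix(c(1, .95, .1, .2,
                .95, 1, .15, .1,
                .1, .15, 1, .9,
                .2, .1, .9, 1), 4, 4)
  labels <- c(1, 1, 2, 2)
  expect_equal(silhouette_width(list(C = C, labels = labels)),
               brute_silhouette(1 - C, labels))
  # perfect blocks
  Cp <- rbind(cbind(matrix(1, 2, 2), matrix(0, 2, 2)),
              cbind(matrix(0, 2, 2), matrix(1, 2, 2)))
  expect_equal(silhouette_width(list(C = Cp, labels = labels)), 1)
  expect_warning(v <- silhouette_width(list(C = Cp, labels = rep(1, 4))),
                 "single cluster")
  expect_true(is.na(v))
})

test_that("permuting samples permutes the consensus matrix conformably", {
  ex <- make_expression(n_genes = 40, n_samples = 20, r = 2, separation = 4,
                        noise = "none", seed = 51)
  X <- ex$matrix
  cc1 <- suppressWarnings(consensus_cluster(X, 2, runs = 8, seed = 52,
                                            max_iter = 200, tol = 1e-8))
  perm <- rev(seq_len(ncol(X)))
  Xp <- expression_matrix(unclass(X)[, perm], "normalized")
  cc2 <- suppressWarnings(consensus_cluster(Xp, 2, runs = 8, seed = 52,
                                            max_iter = 200, tol = 1e-8))
  # noiseless blocks: consensus entries are determined by block membership,
  # so the permuted run's matrix is the conformable permutation
  expect_equal(cc2$C, cc1$C[perm, perm])
})

test_that("rank selection maximizes cophenetic with documented tie-breaks", {
  pick <- function(metrics) {
    coph <- ifelse(is.na(metrics$cophenetic), -Inf, metrics$cophenetic)
    sil <- ifelse(is.na(metrics$silhouette), -Inf, metrics$silhouette)
    metrics$rank[order(-coph, -sil, metrics$rank)][1]
  }
  expect_equal(pick(data.frame(rank = 2:3, cophenetic = c(0.99, 0.90),
                               silhouette = c(0.5, 0.9))), 2)
  expect_equal(pick(data.frame(rank = 2:4, cophenetic = c(0.9, 0.9, 0.9),
                               silhouette = c(0.5, 0.5, 0.5))), 2)
  expect_equal(pick(data.frame(rank = 2:3, cophenetic = c(0.9, 0.9),
                               silhouette = c(0.5, 0.8))), 3)

  ex <- make_expression(n_genes = 60, n_samples = 30, r = 2, separation = 4,
                        noise = "none", seed = 61)
  sel <- suppressWarnings(
    select_rank(ex$matrix, ranks = 2:4, runs = 8, seed = 62,
                max_iter = 200, tol = 1e-8))
  expect_equal(sel$best_rank, 2)
  expect_equal(nrow(sel$metrics), 3)
})

test_that("adjusted Rand index agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(71)
  for (i in 1:5) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  a <- sample(1:3, 30, replace = TRUE)
  expect_equal(adjusted_rand_index(a, a), 1)
})
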