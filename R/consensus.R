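# Subsampled NMF consensus clustering with the cophenetic / dispersion /
# silhouette stability metrics and rank selection.

#' NMF consensus clustering
#'
#' Repeats NMF clustering on random subsamples of the cohort and records, for
#' every pair of samples, the fraction of co-sampled runs in which the pair
#' co-clustered. Final labels come from average-linkage hierarchical
#' clustering of the consensus distance `1 - C` cut at `r` clusters (not from
#' any single NMF run).
#'
#' @param X nonnegative expression matrix (genes x samples), typically the
#'   seed-gene submatrix of a normalized matrix.
#' @param r number of clusters (factorization rank).
#' @param method NMF variant, see [nmf_fit()].
#' @param runs number of subsampled runs; default 50.
#' @param subsample_frac fraction of samples drawn (without replacement) per
#'   run; default 0.8.
#' @param seed master seed; per-run subsampling and initialization seeds are
#'   derived from it with [derive_seed()].
#' @param max_iter,tol passed to [nmf_fit()].
#' @return an object of class `consensus_result`: list with the consensus
#'   matrix `C`, co-sampling count matrix `cosampled`, integer `labels`,
#'   `cophenetic`, `dispersion`, `silhouette`, and the run parameters.
#' @export
consensus_cluster <- function(X, r, method = c("brunet_kl", "lee_frobenius", "offset"),
                              runs = 50, subsample_frac = 0.8, seed = 1,
                              max_iter = 2000, tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(runs >= 2, subsample_frac > 0, subsample_frac <= 1)
  n <- ncol(X)
  n_sub <- floor(subsample_frac * n)
  if (n_sub < r + 1) stop("subsample too small to hold r clusters; raise subsample_frac")

  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (run in seq_len(runs)) {
    set.seed(derive_seed(seed, paste0("subsample", run)))
    idx <- sort(sample.int(n, n_sub))
    fit <- nmf_fit(X[, idx, drop = FALSE], r, method,
                   max_iter = max_iter, tol = tol,
                   seed = derive_seed(seed, paste0("init", run)))
    lab <- assign_labels(fit)
    same <- outer(lab, lab, "==")
    co_cluster[idx, idx] <- co_cluster[idx, idx] + same
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
  }
  C <- matrix(0, n, n)
  seen <- co_sample > 0
  C[seen] <- co_cluster[seen] / co_sample[seen]
  if (any(!seen[upper.tri(seen)])) {
    warning("some sample pairs were never co-sampled; their consensus entries are 0")
  }
  dimnames(C) <- list(colnames(X), colnames(X))

  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  labels <- stats::cutree(hc, k = r)

  res <- structure(
    list(C = C, cosampled = co_sample, labels = labels, rank = r,
         method = method, runs = runs, subsample_frac = subsample_frac,
         seed = seed, hclust = hc,
         cophenetic = NA_real_, dispersion = NA_real_, silhouette = NA_real_),
    class = "consensus_result"
  )
  res$cophenetic <- cophenetic_coefficient(res)
  res$dispersion <- dispersion(res)
  res$silhouette <- silhouette_width(res)
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(paste0("Consensus clustering (%s, r = %d, %d runs, frac %.2f): ",
                     "cophenetic %.4f, dispersion %.4f, silhouette %.4f\n"),
              x$method, x$rank, x$runs, x$subsample_frac,
              x$cophenetic, x$dispersion, x$silhouette))
  cat("cluster sizes:", paste(table(x$labels), collapse = " / "), "\n")
  invisible(x)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Pearson correlation between the consensus distances `1 - C` (upper
#' triangle) and the cophenetic distances of their average-linkage dendrogram.
#' Values near 1 indicate that the consensus matrix is close to a clean block
#' structure.
#'
#' @param result a `consensus_result` (or any list with element `C`).
#' @return numeric in `[-1, 1]`, or `NA` with a warning when the distance
#'   vector is constant (correlation undefined).
#' @export
cophenetic_coefficient <- function(result) {
  d <- stats::as.dist(1 - result$C)
  if (stats::sd(d) == 0) {
    warning("constant consensus distances; cophenetic coefficient undefined")
    return(NA_real_)
  }
  hc <- stats::hclust(d, method = "average")
  cp <- stats::cophenetic(hc)
  if (stats::sd(cp) == 0) {
    warning("constant cophenetic distances; coefficient undefined")
    return(NA_real_)
  }
  stats::cor(as.vector(d), as.vector(cp))
}

#' Dispersion of a consensus matrix
#'
#' Mean of `4 (c - 0.5)^2` over all entries; 1 when every consensus entry is
#' 0 or 1 (perfectly reproducible clustering), 0 when all entries are 0.5.
#'
#' @param result a `consensus_result` (or any list with element `C`).
#' @return numeric in `[0, 1]`.
#' @export
dispersion <- function(result) {
  mean(4 * (result$C - 0.5)^2)
}

#' Mean silhouette width under consensus distances
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` with distance `1 - C` and
#' the consensus labels; singleton clusters contribute `s = 0`.
#'
#' @param result a `consensus_result` (or any list with elements `C` and
#'   `labels`).
#' @return mean silhouette in `[-1, 1]`, or `NA` with a warning when there is
#'   a single cluster.
#' @export
silhouette_width <- function(result) {
  C <- result$C
  labels <- result$labels
  groups <- unique(labels)
  if (length(groups) < 2) {
    warning("single cluster; silhouette undefined")
    return(NA_real_)
  }
  d <- 1 - C
  s <- vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (!length(own)) return(0) # singleton cluster
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(groups, labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Sweep candidate ranks and select the number of subtypes
#'
#' Runs [consensus_cluster()] at each candidate rank and selects the rank
#' maximizing the cophenetic coefficient; exact ties are broken by higher
#' silhouette, then by the smaller rank.
#'
#' @param X nonnegative expression matrix (genes x samples).
#' @param ranks integer vector of candidate ranks; default `2:7`.
#' @param method,runs,subsample_frac,seed,max_iter,tol passed to
#'   [consensus_cluster()]; the per-rank seed is derived from `seed`.
#' @return list with `best_rank`, `metrics` (data.frame of rank, cophenetic,
#'   dispersion, silhouette), and `results` (named list of
#'   `consensus_result`s).
#' @export
select_rank <- function(X, ranks = 2:7, method = c("brunet_kl", "lee_frobenius", "offset"),
                        runs = 50, subsample_frac = 0.8, seed = 1,
                        max_iter = 2000, tol = 1e-6) {
  method <- match.arg(method)
  results <- lapply(ranks, function(r) {
    consensus_cluster(X, r, method, runs = runs, subsample_frac = subsample_frac,
                      seed = derive_seed(seed, paste0("rank", r)),
                      max_iter = max_iter, tol = tol)
  })
  names(results) <- as.character(ranks)
  metrics <- data.frame(
    rank = ranks,
    cophenetic = vapply(results, function(x) x$cophenetic, numeric(1)),
    dispersion = vapply(results, function(x) x$dispersion, numeric(1)),
    silhouette = vapply(results, function(x) x$silhouette, numeric(1)),
    row.names = NULL
  )
  coph <- ifelse(is.na(metrics$cophenetic), -Inf, metrics$cophenetic)
  sil <- ifelse(is.na(metrics$silhouette), -Inf, metrics$silhouette)
  best <- metrics$rank[order(-coph, -sil, metrics$rank)][1]
  list(best_rank = best, metrics = metrics, results = results)
}
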