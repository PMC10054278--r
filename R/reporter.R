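# Reporter-metabolite analysis.
#
# Each gene's differential-expression p-value is converted to a standard
# normal deviate z = qnorm(1 - p). For a metabolite with k scored neighboring
# genes in the enzyme-metabolite bipartite graph, the aggregate score
#
#   Z_raw = (1 / sqrt(k)) * sum(z_i)
#
# is corrected against a size-matched random background: mu_k and sigma_k are
# the mean and standard deviation of the same aggregate over random k-subsets
# of the gene score pool (100,000 sampled sets by default, or exhaustive
# enumeration of all C(N, k) subsets when that is cheaper), and
#
#   Z_corrected = (Z_raw - mu_k) / sigma_k,     p = 1 - Phi(Z_corrected).
#
# Because the correction standardizes by mu_k and sigma_k, any prefactor of
# the form c(k) (1/sqrt(k), 1/k, ...) cancels exactly: Z_corrected is
# invariant to the choice. 1/sqrt(k) is used so that the uncorrected Z_raw is
# itself a standard normal under independent standard-normal neighbor scores.

#' Convert a p-value to a standard-normal deviate
#'
#' `z = qnorm(1 - p)` after clamping `p` into `[eps, 1 - eps]` so extreme
#' p-values stay finite.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param eps clamping bound; default `1e-15`.
#' @return numeric z-score(s).
#' @export
p_to_z <- function(p, eps = 1e-15) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::qnorm(clamp(p, eps, 1 - eps), lower.tail = FALSE)
}

.prefactor <- function(prefactor, k) {
  switch(prefactor, inv_sqrt_k = 1 / sqrt(k), inv_k = 1 / k)
}

#' Aggregate neighbor z-scores for one metabolite
#'
#' @param graph bipartite graph from [build_bipartite_graph()].
#' @param scores data.frame with columns `gene` and `z` (one row per scored
#'   gene).
#' @param metabolite compartment-qualified metabolite id.
#' @param prefactor `"inv_sqrt_k"` (default) or `"inv_k"`; immaterial after
#'   background correction (see module notes).
#' @return list with `z_raw` and `k` (number of scored neighbors); `k = 0`
#'   yields `z_raw = NA` and `skipped = TRUE`.
#' @export
aggregate_metabolite_z <- function(graph, scores, metabolite,
                                   prefactor = c("inv_sqrt_k", "inv_k")) {
  prefactor <- match.arg(prefactor)
  neigh <- metabolite_neighbors(graph, metabolite)
  idx <- match(intersect(neigh, scores$gene), scores$gene)
  k <- length(idx)
  if (k == 0) return(list(z_raw = NA_real_, k = 0L, skipped = TRUE))
  list(z_raw = sum(scores$z[idx]) * .prefactor(prefactor, k),
       k = as.integer(k), skipped = FALSE)
}

#' Background-correct an aggregated metabolite score
#'
#' Draws `n_sets` random k-subsets (without replacement within a set) from
#' the gene score pool, aggregates each with the same prefactor, and
#' standardizes `z_raw` by the mean and standard deviation of those
#' aggregates. When the number of distinct subsets `C(N, k)` does not exceed
#' `n_sets` the enumeration is exhaustive (exact moments) instead of sampled.
#'
#' @param z_raw aggregated score from [aggregate_metabolite_z()].
#' @param k neighborhood size.
#' @param score_pool numeric vector of all gene z-scores forming the
#'   background.
#' @param n_sets number of random sets; default 100000.
#' @param seed integer seed for the sampling path.
#' @param prefactor as in [aggregate_metabolite_z()].
#' @param mode `"auto"` (exhaustive when cheap, else sampled),
#'   `"exhaustive"`, or `"sampling"`.
#' @return list with `z_corrected`, `mu_k`, `sigma_k`, `exhaustive`
#'   (logical), `n_sets_used`, and `error` (`NA` or `"constant_pool"` /
#'   `"zero_sigma"` when the correction is undefined).
#' @export
background_correct <- function(z_raw, k, score_pool, n_sets = 100000, seed = 1,
                               prefactor = c("inv_sqrt_k", "inv_k"),
                               mode = c("auto", "exhaustive", "sampling")) {
  prefactor <- match.arg(prefactor)
  mode <- match.arg(mode)
  N <- length(score_pool)
  stopifnot(k >= 1, N >= k)
  if (length(unique(score_pool)) < 2) {
    return(list(z_corrected = NA_real_, mu_k = NA_real_, sigma_k = 0,
                exhaustive = NA, n_sets_used = 0L, error = "constant_pool"))
  }
  n_subsets <- choose(N, k)
  exhaustive <- switch(mode,
                       auto = n_subsets <= n_sets,
                       exhaustive = TRUE,
                       sampling = FALSE)
  if (exhaustive) {
    if (n_subsets > 1e7) stop("exhaustive enumeration of ", n_subsets, " subsets refused")
    idx <- utils::combn(N, k)
    sums <- .colSums(matrix(score_pool[idx], nrow = k), k, ncol(idx))
    used <- ncol(idx)
  } else {
    set.seed(seed)
    sums <- vapply(seq_len(n_sets),
                   function(i) sum(score_pool[sample.int(N, k)]),
                   numeric(1))
    used <- n_sets
  }
  agg <- sums * .prefactor(prefactor, k)
  mu <- mean(agg)
  sigma <- sqrt(mean((agg - mu)^2))
  if (sigma <= 0) {
    return(list(z_corrected = NA_real_, mu_k = mu, sigma_k = 0,
                exhaustive = exhaustive, n_sets_used = as.integer(used),
                error = "zero_sigma"))
  }
  list(z_corrected = (z_raw - mu) / sigma, mu_k = mu, sigma_k = sigma,
       exhaustive = exhaustive, n_sets_used = as.integer(used), error = NA_character_)
}

#' Reporter-metabolite analysis
#'
#' Scores every metabolite of the bipartite graph against a gene-level
#' differential-expression table, corrects each aggregate against a
#' size-matched random background, and returns metabolites passing the
#' neighborhood-size and significance filters.
#'
#' Directional modes restrict the score table (and the background pool) to
#' genes of one fold-change sign before scoring: `"up"` keeps genes with
#' `log2FC > 0`, `"down"` genes with `log2FC < 0`, `"all"` keeps everything.
#' The scored-neighbor count `k` therefore counts same-direction neighbors
#' only, and `min_k` applies to that count.
#'
#' @param graph bipartite graph from [build_bipartite_graph()].
#' @param de DE table with columns `gene`, `log2FC`, `p_value`.
#' @param mode `"all"`, `"up"` or `"down"`.
#' @param min_k minimum number of scored neighboring genes; default 3.
#' @param alpha reporter p-value threshold; default 0.05.
#' @param n_sets background sets per neighborhood size; default 100000.
#' @param seed master seed; one background seed per distinct `k` is derived
#'   from it, so results do not depend on metabolite iteration order.
#' @param prefactor see [aggregate_metabolite_z()].
#' @param background `"all_scored"` (default: every gene in the mode's score
#'   table) or `"graph_only"` (restrict the pool to graph member genes).
#' @return data.frame of significant metabolites (columns `metabolite`,
#'   `compartment`, `k`, `z_raw`, `mu_k`, `sigma_k`, `z_corrected`,
#'   `p_value`, `mode`), sorted by p-value; the unfiltered table of all
#'   scoreable metabolites is attached as attribute `"all_metabolites"` and
#'   skipped/flagged metabolites as attribute `"skipped"`.
#' @export
reporter_metabolites <- function(graph, de, mode = c("all", "up", "down"),
                                 min_k = 3, alpha = 0.05, n_sets = 100000,
                                 seed = 1, prefactor = c("inv_sqrt_k", "inv_k"),
                                 background = c("all_scored", "graph_only")) {
  mode <- match.arg(mode)
  prefactor <- match.arg(prefactor)
  background <- match.arg(background)
  if (!nrow(de)) stop("empty differential-expression table")

  keep <- switch(mode,
                 all = rep(TRUE, nrow(de)),
                 up = de$log2FC > 0,
                 down = de$log2FC < 0)
  scores <- data.frame(gene = de$gene[keep],
                       z = p_to_z(de$p_value[keep]),
                       stringsAsFactors = FALSE)
  if (!nrow(scores)) stop("no genes left after directional restriction")
  if (background == "graph_only") {
    member <- igraph::V(graph)$name[igraph::V(graph)$type]
    scores <- scores[scores$gene %in% member, , drop = FALSE]
    if (!nrow(scores)) stop("no scored genes are members of the graph")
  }
  pool <- scores$z

  mets <- graph_metabolites(graph)
  bg_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(mets))
  skipped <- character(0)
  for (i in seq_along(mets)) {
    m <- mets[i]
    agg <- aggregate_metabolite_z(graph, scores, m, prefactor)
    if (agg$skipped) {
      skipped <- c(skipped, m)
      next
    }
    key <- as.character(agg$k)
    if (is.null(bg_cache[[key]])) {
      bg_cache[[key]] <- background_correct(
        0, agg$k, pool, n_sets = n_sets,
        seed = derive_seed(seed, paste0("k", agg$k)), prefactor = prefactor)
    }
    bg <- bg_cache[[key]]
    if (!is.na(bg$error)) {
      skipped <- c(skipped, m)
      next
    }
    zc <- (agg$z_raw - bg$mu_k) / bg$sigma_k
    rows[[i]] <- data.frame(
      metabolite = m, compartment = compartment_of(m), k = agg$k,
      z_raw = agg$z_raw, mu_k = bg$mu_k, sigma_k = bg$sigma_k,
      z_corrected = zc, p_value = stats::pnorm(zc, lower.tail = FALSE),
      mode = mode, stringsAsFactors = FALSE
    )
  }
  all_tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(all_tab)) {
    all_tab <- data.frame(metabolite = character(0), compartment = character(0),
                          k = integer(0), z_raw = numeric(0), mu_k = numeric(0),
                          sigma_k = numeric(0), z_corrected = numeric(0),
                          p_value = numeric(0), mode = character(0),
                          stringsAsFactors = FALSE)
  }
  all_tab <- all_tab[order(all_tab$p_value, all_tab$metabolite), , drop = FALSE]
  rownames(all_tab) <- NULL
  out <- all_tab[all_tab$k >= min_k & all_tab$p_value < alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_metabolites") <- all_tab
  attr(out, "skipped") <- skipped
  out
}
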