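# Synthetic-data generators with planted ground truth.
#
# Each generator is a pure function of (parameters, seed) and returns the
# planted truth alongside the data, so every pipeline stage can be validated
# without external data: low-rank two-subtype expression for the clustering
# stage, a toy metabolic model with plantable dysregulated neighborhoods for
# the reporter stage, subtype-dependent survival, subtype-associated
# categorical covariates with a target Cramer's V, and subtype-enriched
# mutations with plantable mutually exclusive pairs.

#' Simulate a low-rank two-subtype expression count matrix
#'
#' Builds a block-structured basis matrix `W` (each rank owns a contiguous
#' gene block whose loadings are elevated by `separation` over a small
#' background) and a one-hot-plus-noise meta-profile matrix `H`, then draws
#' counts around `base_scale * W %*% H` with Poisson or negative-binomial
#' noise.
#'
#' @param n_genes,n_samples matrix dimensions; defaults 1000 x 100.
#' @param r number of planted subtypes; default 2.
#' @param separation elevation of in-block loadings over the ~0.1 background;
#'   default 4 (strongly separated subtypes, the regime of a cohort whose
#'   consensus clustering is near-perfectly stable).
#' @param noise `"nb"` (negative binomial, the RNA-seq-like default),
#'   `"poisson"`, or `"none"` (return the noiseless mean matrix, tagged
#'   `normalized` since it is not integer counts).
#' @param dispersion NB dispersion (`1/size`); default 0.1.
#' @param base_scale multiplier setting the count scale; default 30.
#' @param shared_frac fraction of genes (taken from the end of the matrix)
#'   given elevated loadings in every rank instead of one block: these genes
#'   are expressed but carry no subtype signal, emulating the bulk of a real
#'   transcriptome that is not differential; recorded with block 0 in the
#'   truth. Default 0.
#' @param seed integer seed.
#' @return list with `matrix` (an [expression_matrix()]) and `truth` (planted
#'   `labels`, `W`, `H`, block assignment, parameters, `seed`).
#' @export
make_expression <- function(n_genes = 1000, n_samples = 100, r = 2,
                            separation = 4, noise = c("nb", "poisson", "none"),
                            dispersion = 0.1, base_scale = 30,
                            shared_frac = 0, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(r >= 1, n_samples >= r, shared_frac >= 0, shared_frac < 1)
  n_shared <- round(shared_frac * n_genes)
  n_block <- n_genes - n_shared
  stopifnot(n_block >= r)
  set.seed(seed)
  gene_block <- c(sort(rep(seq_len(r), length.out = n_block)),
                  rep(0L, n_shared))
  W <- matrix(stats::runif(n_genes * r, 0.05, 0.15), n_genes, r)
  blocked <- which(gene_block > 0)
  idx <- cbind(blocked, gene_block[blocked])
  W[idx] <- W[idx] + separation * stats::runif(length(blocked), 0.8, 1.2)
  shared <- which(gene_block == 0)
  if (length(shared)) {
    W[shared, ] <- W[shared, ] +
      separation * stats::runif(length(shared), 0.8, 1.2)
  }
  labels <- sample(rep(seq_len(r), length.out = n_samples))
  H <- matrix(stats::runif(r * n_samples, 0, 0.05), r, n_samples)
  H[cbind(labels, seq_len(n_samples))] <- 1
  mu <- base_scale * W %*% H
  vals <- switch(noise,
                 none = mu,
                 poisson = matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu)),
                 nb = matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                             nrow(mu), ncol(mu)))
  rownames(vals) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(vals) <- sprintf("sample%03d", seq_len(n_samples))
  mat <- expression_matrix(vals + 0, if (noise == "none") "normalized" else "raw_counts")
  truth <- list(labels = stats::setNames(labels, colnames(vals)),
                gene_block = stats::setNames(gene_block, rownames(vals)),
                W = W, H = H, r = r, separation = separation, noise = noise,
                dispersion = dispersion, base_scale = base_scale,
                shared_frac = shared_frac, seed = seed)
  list(matrix = mat, truth = truth)
}

#' Simulate a toy metabolic model
#'
#' One reaction per metabolite; each metabolite's gene set mixes private
#' genes with draws from a shared pool according to `overlap` (0 = fully
#' disjoint neighborhoods, 1 = all genes drawn from one shared pool).
#' Compartment tags are assigned round-robin from `{c, m, n}`.
#'
#' @param n_metabolites number of metabolites/reactions; default 60.
#' @param genes_per_met genes per reaction; default 5.
#' @param overlap shared-gene fraction in `[0, 1]`; default 0.
#' @param seed integer seed.
#' @return list with `model` (a [metabolic_model()]) and `truth`.
#' @export
make_toy_model <- function(n_metabolites = 60, genes_per_met = 5,
                           overlap = 0, seed = 1) {
  stopifnot(n_metabolites >= 1, genes_per_met >= 1, overlap >= 0, overlap <= 1)
  set.seed(seed)
  n_shared_draw <- round(genes_per_met * overlap)
  n_private <- genes_per_met - n_shared_draw
  shared_pool <- sprintf("gs%03d", seq_len(max(2 * genes_per_met, 4)))
  comps <- c("c", "m", "n")
  reactions <- vector("list", n_metabolites)
  for (i in seq_len(n_metabolites)) {
    private <- if (n_private > 0) sprintf("gp%03d_%02d", i, seq_len(n_private)) else character(0)
    shared <- if (n_shared_draw > 0) sample(shared_pool, n_shared_draw) else character(0)
    met <- sprintf("met%03d[%s]", i, comps[(i - 1) %% 3 + 1])
    reactions[[i]] <- list(id = sprintf("R%03d", i),
                           genes = c(private, shared), metabolites = met)
  }
  model <- metabolic_model(reactions)
  truth <- list(n_metabolites = n_metabolites, genes_per_met = genes_per_met,
                overlap = overlap, shared_pool = shared_pool, seed = seed)
  list(model = model, truth = truth)
}

#' Simulate a differential-expression table with planted reporter signal
#'
#' Genes neighboring the planted metabolites receive one-sided p-values from
#' `z ~ Normal(effect, 1)` (`p = 1 - Phi(z)`) and positive fold changes;
#' every other model gene gets `p ~ Uniform(0, 1)` and a small fold change
#' of random sign.
#'
#' @param model a [metabolic_model()].
#' @param planted_mets metabolite ids (compartment-qualified or bare) whose
#'   gene neighborhoods carry the signal; empty for a pure null table.
#' @param effect mean of the planted z-shift; default 3.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `log2FC`, `p_value`, `adj_p`;
#'   planted metabolites and genes attached as attribute `"truth"`.
#' @export
make_de_scores <- function(model, planted_mets = character(), effect = 3, seed = 1) {
  stopifnot(inherits(model, "metabolic_model"))
  set.seed(seed)
  genes <- sort(model$genes)
  planted_genes <- unique(unlist(lapply(model$reactions, function(r) {
    hit <- r$metabolites %in% planted_mets |
      strip_compartment(r$metabolites) %in% planted_mets
    if (any(hit)) r$genes else NULL
  })))
  is_planted <- genes %in% planted_genes
  p <- stats::runif(length(genes))
  z <- stats::rnorm(sum(is_planted), mean = effect, sd = 1)
  p[is_planted] <- stats::pnorm(z, lower.tail = FALSE)
  lfc <- stats::rnorm(length(genes), 0, 0.5)
  lfc[is_planted] <- abs(stats::rnorm(sum(is_planted), 1.5, 0.5)) + 0.1
  out <- data.frame(gene = genes, log2FC = lfc, p_value = p,
                    adj_p = bh_adjust(p), stringsAsFactors = FALSE)
  attr(out, "truth") <- list(planted_mets = planted_mets,
                             planted_genes = planted_genes,
                             effect = effect, seed = seed)
  out
}

#' Simulate subtype-dependent survival
#'
#' Exponential event times whose hazard is multiplied by `hazard_ratio` for
#' every step above the first group level; censoring is applied
#' independently: with probability `censor_frac` a record is censored at a
#' uniform time before its event.
#'
#' @param labels subtype label vector (names become sample ids; otherwise
#'   ids are generated).
#' @param hazard_ratio per-group hazard multiplier; default 2.
#' @param baseline_rate exponential hazard of the first group; default 0.1.
#' @param censor_frac expected censored fraction; default 0.2.
#' @param seed integer seed.
#' @return survival data.frame with columns `sample`, `time`, `event`,
#'   `group`.
#' @export
make_survival <- function(labels, hazard_ratio = 2, baseline_rate = 0.1,
                          censor_frac = 0.2, seed = 1) {
  stopifnot(censor_frac >= 0, censor_frac < 1)
  set.seed(seed)
  n <- length(labels)
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(n))
  grp <- as.integer(factor(labels))
  rate <- baseline_rate * hazard_ratio^(grp - 1)
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < censor_frac
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  data.frame(sample = ids, time = time, event = as.integer(!censored),
             group = as.vector(labels), stringsAsFactors = FALSE)
}

# Expected population Cramer's V of the mixture generator for mixing weight
# w: with probability w a sample's category is a deterministic function of
# its subtype, otherwise uniform over the categories.
.expected_v <- function(w, p_s, n_categories) {
  r <- length(p_s)
  f <- ((seq_len(r) - 1) %% n_categories) + 1
  p_sc <- matrix(0, r, n_categories)
  for (s in seq_len(r)) {
    p_sc[s, ] <- p_s[s] * (1 - w) / n_categories
    p_sc[s, f[s]] <- p_sc[s, f[s]] + p_s[s] * w
  }
  p_c <- colSums(p_sc)
  used <- p_c > 0
  e <- outer(p_s, p_c[used])
  phi2 <- sum((p_sc[, used, drop = FALSE] - e)^2 / e)
  sqrt(phi2 / (min(r, sum(used)) - 1))
}

#' Simulate a categorical clinical covariate with a target Cramer's V
#'
#' Each sample's category is, with mixing weight `w`, a deterministic map of
#' its subtype and otherwise uniform noise; `w` is solved by bisection so the
#' population Cramer's V of the implied probability table equals `target_v`.
#'
#' @param labels subtype label vector.
#' @param target_v desired association strength in `[0, 1]`; default 0.6.
#' @param n_categories number of categories; default 4.
#' @param seed integer seed.
#' @return character vector of categories (`"cat1"`, ...); the solved mixing
#'   weight is attached as attribute `"mixing_weight"`.
#' @export
make_clinical <- function(labels, target_v = 0.6, n_categories = 4, seed = 1) {
  stopifnot(target_v >= 0, target_v <= 1, n_categories >= 2)
  grp <- as.integer(factor(labels))
  p_s <- as.vector(table(grp)) / length(grp)
  if (length(p_s) < 2) stop("need at least two subtypes")
  w <- if (target_v >= 1) 1 else if (target_v <= 0) 0 else {
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (.expected_v(mid, p_s, n_categories) < target_v) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  set.seed(seed)
  f <- ((seq_len(max(grp)) - 1) %% n_categories) + 1
  deterministic <- stats::runif(length(grp)) < w
  cats <- ifelse(deterministic, f[grp],
                 sample.int(n_categories, length(grp), replace = TRUE))
  out <- paste0("cat", cats)
  attr(out, "mixing_weight") <- w
  out
}

#' Simulate a MAF with planted differential and mutually exclusive genes
#'
#' Planted genes mutate per sample with group-specific Bernoulli
#' frequencies; background genes mutate at a flat rate in all samples; each
#' exclusive pair draws its mutated samples from two disjoint halves of the
#' cohort so the pair never co-occurs. A sprinkling of `Silent` records is
#' added so the non-synonymous filter has work to do.
#'
#' @param labels subtype label vector, named by sample id (exactly two
#'   groups).
#' @param planted_genes data.frame with columns `gene`, `freq_group1`,
#'   `freq_group2`; default plants one strongly differential gene
#'   (0.9 vs 0.3).
#' @param exclusive_pairs list of character pairs `c(geneA, geneB)`.
#' @param pair_freq overall mutation frequency of each exclusive-pair gene;
#'   default 0.5.
#' @param background_genes character vector of background genes; default 20
#'   genes.
#' @param background_freq flat background mutation rate; default 0.1.
#' @param seed integer seed.
#' @param path optional path; when given, the table is written as a valid
#'   MAF.
#' @return a `maf_table` data.frame; planted structure attached as attribute
#'   `"truth"`.
#' @export
make_maf <- function(labels,
                     planted_genes = data.frame(gene = "MUTD1",
                                                freq_group1 = 0.9,
                                                freq_group2 = 0.3),
                     exclusive_pairs = list(),
                     pair_freq = 0.5,
                     background_genes = sprintf("BG%02d", 1:20),
                     background_freq = 0.1, seed = 1, path = NULL) {
  if (is.null(names(labels))) {
    names(labels) <- sprintf("sample%03d", seq_along(labels))
  }
  groups <- sort(unique(as.character(labels)))
  if (length(groups) != 2) stop("labels must define exactly two groups")
  set.seed(seed)
  samples <- names(labels)
  n <- length(samples)
  rows <- list()
  add <- function(gene, who, class = "Missense_Mutation") {
    if (!length(who)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      Hugo_Symbol = gene, Tumor_Sample_Barcode = who,
      Variant_Classification = class, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(planted_genes))) {
    freq <- ifelse(labels == groups[1],
                   planted_genes$freq_group1[i], planted_genes$freq_group2[i])
    add(planted_genes$gene[i], samples[stats::runif(n) < freq])
  }
  pair_samples <- list()
  for (pr in exclusive_pairs) {
    half <- sample(samples, floor(n / 2))
    other <- setdiff(samples, half)
    p_in <- min(1, pair_freq * n / length(half))
    a <- half[stats::runif(length(half)) < p_in]
    b <- other[stats::runif(length(other)) < min(1, pair_freq * n / length(other))]
    add(pr[1], a)
    add(pr[2], b)
    pair_samples[[paste(pr, collapse = "|")]] <- list(a = a, b = b)
  }
  for (g in background_genes) {
    add(g, samples[stats::runif(n) < background_freq])
  }
  # silent records: ignored by every non-synonymous count
  add("BGSIL", samples[stats::runif(n) < 0.05], class = "Silent")
  out <- do.call(rbind, rows)
  out <- out[order(out$Hugo_Symbol, out$Tumor_Sample_Barcode), , drop = FALSE]
  rownames(out) <- NULL
  maf <- data.frame(gene = out$Hugo_Symbol, sample = out$Tumor_Sample_Barcode,
                    classification = out$Variant_Classification,
                    stringsAsFactors = FALSE)
  maf$nonsynonymous <- maf$classification %in% nonsynonymous_classes
  class(maf) <- c("maf_table", class(maf))
  attr(maf, "truth") <- list(planted_genes = planted_genes,
                             exclusive_pairs = exclusive_pairs,
                             pair_samples = pair_samples,
                             background_genes = background_genes,
                             background_freq = background_freq, seed = seed)
  if (!is.null(path)) write_tsv(out, path)
  maf
}
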