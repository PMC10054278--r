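# Per-subtype somatic mutation statistics from MAF input: mutation
# frequency, tumor mutation burden, differential mutation between subtypes,
# and pairwise co-occurrence / mutual exclusivity.

#' Non-synonymous variant classifications
#'
#' The MAF variant classes counted as non-synonymous throughout the module.
#' @export
nonsynonymous_classes <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "Splice_Site", "In_Frame_Del", "In_Frame_Ins",
  "Translation_Start_Site", "Nonstop_Mutation"
)

.known_maf_classes <- c(
  nonsynonymous_classes,
  "Silent", "Splice_Region", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
  "Intron", "RNA", "IGR", "Targeted_Region"
)

#' Read a MAF file
#'
#' Requires the columns `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`. Records with classifications outside the MAF
#' controlled vocabulary are retained but excluded from the non-synonymous
#' subset, with a warning.
#'
#' @param path path to a tab-separated MAF (GDC dialect; `#` comment lines
#'   allowed).
#' @return data.frame of class `maf_table` with columns `gene`, `sample`,
#'   `classification`, `nonsynonymous` (logical).
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("MAF is missing columns: ", paste(missing, collapse = ", "))
  unknown <- setdiff(unique(df$Variant_Classification), .known_maf_classes)
  if (length(unknown)) {
    warning("unknown variant classification(s) excluded from the non-synonymous subset: ",
            paste(unknown, collapse = ", "))
  }
  out <- data.frame(gene = df$Hugo_Symbol,
                    sample = df$Tumor_Sample_Barcode,
                    classification = df$Variant_Classification,
                    stringsAsFactors = FALSE)
  out$nonsynonymous <- out$classification %in% nonsynonymous_classes
  class(out) <- c("maf_table", class(out))
  out
}

as_maf_table <- function(maf) {
  stopifnot(is.data.frame(maf), all(c("gene", "sample") %in% names(maf)))
  if (is.null(maf$nonsynonymous)) {
    maf$nonsynonymous <- maf$classification %in% nonsynonymous_classes
  }
  maf
}

#' Per-gene mutation frequency in a cohort
#'
#' A sample counts once per gene regardless of how many variants it carries;
#' only non-synonymous records are counted.
#'
#' @param maf a `maf_table` from [read_maf()].
#' @param cohort character vector of sample ids defining the denominator.
#' @return data.frame with columns `gene`, `n_mutated`, `frequency`, sorted
#'   by decreasing frequency (ties by gene id).
#' @export
mutation_frequency <- function(maf, cohort) {
  maf <- as_maf_table(maf)
  stopifnot(length(cohort) > 0)
  sub <- maf[maf$nonsynonymous & maf$sample %in% cohort, c("gene", "sample")]
  pairs <- unique(sub)
  counts <- table(pairs$gene)
  out <- data.frame(gene = names(counts), n_mutated = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$frequency <- out$n_mutated / length(cohort)
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor mutation burden
#'
#' Non-synonymous mutations per megabase of captured genome, per sample and
#' averaged over the cohort; cohort samples with no MAF records count as 0.
#'
#' @param maf a `maf_table`.
#' @param cohort character vector of sample ids.
#' @param capture_size_mb capture size in megabases; default 38 (a common
#'   whole-exome convention — the denominator is configurable because
#'   published TMB values rarely state it).
#' @param variants `"nonsynonymous"` (default) or `"all"`.
#' @return list with `per_sample` (data.frame `sample`, `n_mutations`,
#'   `tmb`) and `mean_tmb`.
#' @export
tmb <- function(maf, cohort, capture_size_mb = 38,
                variants = c("nonsynonymous", "all")) {
  maf <- as_maf_table(maf)
  variants <- match.arg(variants)
  stopifnot(length(cohort) > 0, capture_size_mb > 0)
  sub <- maf[maf$sample %in% cohort, , drop = FALSE]
  if (variants == "nonsynonymous") sub <- sub[sub$nonsynonymous, , drop = FALSE]
  counts <- table(factor(sub$sample, levels = cohort))
  per <- data.frame(sample = cohort, n_mutations = as.integer(counts),
                    stringsAsFactors = FALSE)
  per$tmb <- per$n_mutations / capture_size_mb
  list(per_sample = per, mean_tmb = mean(per$tmb))
}

#' Differentially mutated genes between two groups
#'
#' Genes with a total mutated-sample count of at least `min_freq` are tested
#' with a two-sided Fisher's exact test on the 2x2 table of mutation status
#' by group.
#'
#' @param maf a `maf_table`.
#' @param labels named vector mapping sample id to group (exactly two
#'   groups).
#' @param min_freq minimum total mutated-sample count for a gene to be
#'   tested; default 10.
#' @param alpha significance threshold on the raw Fisher p; default 0.01.
#' @return data.frame with per-gene counts and frequencies per group, odds
#'   ratio (group-1 relative odds of mutation), Fisher `p`, `enriched_group`
#'   and `significant`, sorted by p.
#' @export
differential_mutation <- function(maf, labels, min_freq = 10, alpha = 0.01) {
  maf <- as_maf_table(maf)
  if (is.null(names(labels))) stop("labels must be named by sample id")
  groups <- sort(unique(as.character(labels)))
  if (length(groups) != 2) stop("labels must define exactly two groups")
  s1 <- names(labels)[labels == groups[1]]
  s2 <- names(labels)[labels == groups[2]]
  if (!length(s1) || !length(s2)) stop("both groups must be non-empty")

  sub <- unique(maf[maf$nonsynonymous & maf$sample %in% names(labels),
                    c("gene", "sample")])
  n1 <- table(factor(sub$gene[sub$sample %in% s1]))
  n2 <- table(factor(sub$gene[sub$sample %in% s2]))
  genes <- sort(unique(sub$gene))
  c1 <- as.integer(n1[match(genes, names(n1))]); c1[is.na(c1)] <- 0L
  c2 <- as.integer(n2[match(genes, names(n2))]); c2[is.na(c2)] <- 0L
  keep <- (c1 + c2) >= min_freq
  genes <- genes[keep]; c1 <- c1[keep]; c2 <- c2[keep]
  N1 <- length(s1); N2 <- length(s2)

  rows <- lapply(seq_along(genes), function(i) {
    tab <- matrix(c(c1[i], N1 - c1[i], c2[i], N2 - c2[i]), 2, 2, byrow = TRUE)
    p <- fisher_exact(tab)
    or_num <- c1[i] * (N2 - c2[i])
    or_den <- (N1 - c1[i]) * c2[i]
    or <- if (or_den == 0) { if (or_num == 0) NaN else Inf } else or_num / or_den
    f1 <- c1[i] / N1; f2 <- c2[i] / N2
    enriched <- if (f1 > f2) groups[1] else if (f2 > f1) groups[2] else "none"
    data.frame(gene = genes[i], n_group1 = c1[i], n_group2 = c2[i],
               freq_group1 = f1, freq_group2 = f2, odds_ratio = or,
               p = p, enriched_group = enriched, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), n_group1 = integer(0),
                      n_group2 = integer(0), freq_group1 = numeric(0),
                      freq_group2 = numeric(0), odds_ratio = numeric(0),
                      p = numeric(0), enriched_group = character(0),
                      stringsAsFactors = FALSE)
  }
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  out
}

#' Pairwise co-occurrence / mutual exclusivity of frequently mutated genes
#'
#' Takes the `top_n` most frequently mutated genes in the cohort and, for
#' every unordered pair, tests the 2x2 table of per-sample mutation status
#' with a two-sided Fisher's exact test. A pair is labeled co-occurring when
#' the sample odds ratio exceeds 1, mutually exclusive when below 1, and
#' `"none"` at exactly 1; identical mutation sets give an infinite odds
#' ratio (reported as `Inf`).
#'
#' @param maf a `maf_table`.
#' @param cohort character vector of sample ids.
#' @param top_n number of most frequently mutated genes to test; default 20.
#' @return data.frame with columns `gene_a`, `gene_b`, `n_both`, `n_a_only`,
#'   `n_b_only`, `n_neither`, `odds_ratio`, `p`, `p_adj` (BH), `relation`.
#' @export
cooccurrence <- function(maf, cohort, top_n = 20) {
  maf <- as_maf_table(maf)
  freq <- mutation_frequency(maf, cohort)
  genes <- utils::head(freq$gene, top_n)
  if (length(genes) < 2) stop("fewer than two mutated genes in the cohort")
  sub <- unique(maf[maf$nonsynonymous & maf$sample %in% cohort, c("gene", "sample")])
  status <- vapply(genes, function(g) cohort %in% sub$sample[sub$gene == g],
                   logical(length(cohort)))
  pairs <- utils::combn(length(genes), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- sum(status[, i1] & status[, i2])
    b <- sum(status[, i1] & !status[, i2])
    c_ <- sum(!status[, i1] & status[, i2])
    d <- sum(!status[, i1] & !status[, i2])
    p <- fisher_exact(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))
    or <- if (b * c_ == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c_)
    relation <- if (is.nan(or)) "none"
      else if (or > 1) "co-occurring"
      else if (or < 1) "mutually_exclusive"
      else "none"
    data.frame(gene_a = genes[i1], gene_b = genes[i2], n_both = a,
               n_a_only = b, n_b_only = c_, n_neither = d,
               odds_ratio = or, p = p, relation = relation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
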