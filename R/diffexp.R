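# Differential expression: a transparent built-in two-group test on
# normalized data, ingestion of external DE tables (e.g. DESeq2 or limma
# output), and the fold-change / adjusted-p DEG filter.
#
# The built-in test is a stand-in: the pipeline consumes DE statistics, it
# does not redefine them, so externally computed tables are first-class
# inputs via read_de_table().

#' Built-in two-group differential expression test
#'
#' Per gene, `log2FC` is the difference of group means on the log2 scale
#' (group 2 minus group 1, i.e. the second factor level relative to the
#' first), and the p-value comes from a Welch t-test or a Wilcoxon rank-sum
#' test. Adjusted p-values are Benjamini-Hochberg over all tested genes.
#'
#' @param x normalized expression matrix (genes x samples).
#' @param labels two-group vector aligned with the columns of `x` (coerced to
#'   factor; the first level is the reference group).
#' @param test `"welch_t"` (default) or `"wilcoxon"`.
#' @return data.frame with columns `gene`, `log2FC`, `p_value`, `adj_p`,
#'   `flag` (`"constant"` for genes degenerate under the t-test, which get
#'   `p = 1`).
#' @export
builtin_de_test <- function(x, labels, test = c("welch_t", "wilcoxon")) {
  test <- match.arg(test)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must define exactly two groups")
  if (length(labels) != ncol(x)) stop("labels must match the number of samples")
  g1 <- which(labels == levels(labels)[1])
  g2 <- which(labels == levels(labels)[2])
  if (length(g1) < 2 || length(g2) < 2) stop("both groups need at least 2 samples")

  lfc <- rowMeans(x[, g2, drop = FALSE]) - rowMeans(x[, g1, drop = FALSE])
  p <- numeric(nrow(x))
  flag <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    a <- x[i, g1]; b <- x[i, g2]
    if (test == "welch_t") {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        p[i] <- 1
        flag[i] <- "constant"
      } else {
        p[i] <- stats::t.test(b, a)$p.value
      }
    } else {
      p[i] <- suppressWarnings(stats::wilcox.test(b, a, exact = FALSE)$p.value)
    }
  }
  data.frame(gene = rownames(x), log2FC = unname(lfc), p_value = p,
             adj_p = bh_adjust(p), flag = flag, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; monotone in the sorted p order and
#' capped at 1.
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Read an external differential-expression table
#'
#' Accepts DESeq2-style TSV output by default; column aliases are
#' configurable. Rows with missing p-values are dropped (count reported). If
#' the adjusted-p column is absent it is recomputed with [bh_adjust()] and a
#' warning is issued.
#'
#' @param path path to the TSV.
#' @param aliases named list of accepted column names for `gene`, `log2fc`,
#'   `pvalue`, `padj`.
#' @return data.frame with columns `gene`, `log2FC`, `p_value`, `adj_p`.
#' @export
read_de_table <- function(path,
                          aliases = list(
                            gene = c("gene", "gene_id", "Gene"),
                            log2fc = c("log2FoldChange", "log2FC", "logFC"),
                            pvalue = c("pvalue", "p_value", "PValue", "P.Value"),
                            padj = c("padj", "adj_p", "adj.P.Val", "FDR"))) {
  df <- read_tsv(path)
  if (!nrow(df) && !ncol(df)) stop("empty DE table: ", path)
  find <- function(keys) {
    hit <- intersect(keys, names(df))
    if (length(hit)) hit[1] else NA_character_
  }
  gene_col <- find(aliases$gene)
  # tolerate gene ids in an unnamed first column (DESeq2 row names)
  if (is.na(gene_col) && !is.numeric(df[[1]])) gene_col <- names(df)[1]
  lfc_col <- find(aliases$log2fc)
  p_col <- find(aliases$pvalue)
  if (is.na(gene_col) || is.na(lfc_col) || is.na(p_col)) {
    stop("DE table must provide gene, log2 fold-change and p-value columns")
  }
  lfc <- df[[lfc_col]]
  if (!is.numeric(lfc)) {
    suppressWarnings(num <- as.numeric(lfc))
    bad <- which(is.na(num) & !is.na(lfc) & nzchar(trimws(lfc)))
    if (length(bad)) {
      stop("non-numeric log2 fold change in row(s): ", paste(bad, collapse = ", "))
    }
    lfc <- num
  }
  out <- data.frame(gene = as.character(df[[gene_col]]), log2FC = lfc,
                    p_value = as.numeric(df[[p_col]]), stringsAsFactors = FALSE)
  padj_col <- find(aliases$padj)
  if (is.na(padj_col)) {
    warning("adjusted-p column absent; recomputing with Benjamini-Hochberg")
    out$adj_p <- bh_adjust(out$p_value)
  } else {
    out$adj_p <- as.numeric(df[[padj_col]])
  }
  drop <- is.na(out$p_value)
  if (any(drop)) {
    message(sprintf("read_de_table: dropped %d row(s) with missing p-values", sum(drop)))
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Apply the DEG thresholds
#'
#' Strict inequalities: upregulated means `log2FC > lfc_cut`, downregulated
#' `log2FC < -lfc_cut`, both with `adj_p < alpha`.
#'
#' @param records DE data.frame with columns `gene`, `log2FC`, `adj_p`.
#' @param lfc_cut absolute log2 fold-change threshold; default 1.
#' @param alpha adjusted-p threshold; default 0.05.
#' @return list with character vectors `up` and `down`.
#' @export
filter_degs <- function(records, lfc_cut = 1, alpha = 0.05) {
  sig <- !is.na(records$adj_p) & records$adj_p < alpha
  list(up = records$gene[sig & records$log2FC > lfc_cut],
       down = records$gene[sig & records$log2FC < -lfc_cut])
}
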