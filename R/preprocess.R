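# Expression normalization, restriction to model genes, and MAD-based
# selection of the high-variability seed gene list for clustering.

#' Tag and validate an expression matrix
#'
#' Expression data travel through the pipeline as a plain numeric matrix
#' (genes x samples) carrying an `expr_scale` attribute, either
#' `"raw_counts"` or `"normalized"`.
#'
#' @param values numeric matrix with unique row (gene) and column (sample)
#'   names and no negative entries.
#' @param scale `"raw_counts"` or `"normalized"`.
#' @return the matrix with its `expr_scale` attribute set.
#' @export
expression_matrix <- function(values, scale = c("raw_counts", "normalized")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(values < 0)) stop("expression matrix has negative entries")
  attr(values, "expr_scale") <- scale
  values
}

#' @rdname expression_matrix
#' @param x a matrix.
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "expr_scale")
  if (is.null(sc)) NA_character_ else sc
}

#' Read a genes-x-samples expression TSV
#'
#' First column holds gene ids, the header row sample ids.
#'
#' @param path path to the TSV.
#' @param scale scale flag to attach, see [expression_matrix()].
#' @return an expression matrix.
#' @export
read_expression_tsv <- function(path, scale = c("raw_counts", "normalized")) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, match.arg(scale))
}

#' Write an expression matrix as TSV
#'
#' @param x expression matrix.
#' @param path output path.
#' @param id_column header name of the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_column = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write_tsv(df, path)
}

#' Library-size normalization of raw counts
#'
#' Median-of-ratios size factors (the DESeq-style estimator): the reference
#' is the per-gene geometric mean over samples, computed on genes with all
#' positive counts; each sample's size factor is the median ratio of its
#' counts to the reference. The output is `log2(count / size_factor + 1)`.
#' This is a variance-comparable stand-in for a full variance-stabilizing
#' transform; externally normalized matrices are accepted anywhere a
#' normalized matrix is expected.
#'
#' @param counts raw-count expression matrix (integer-valued, nonnegative).
#' @param pseudo_reference if no gene has all-positive counts the geometric
#'   mean reference is undefined; set `TRUE` to compute the reference over
#'   positive counts only (a "poscounts"-style fallback).
#' @return a normalized expression matrix; size factors are attached as the
#'   `size_factors` attribute.
#' @export
normalize_counts <- function(counts, pseudo_reference = FALSE) {
  if (!identical(expr_scale(counts), "raw_counts")) {
    stop("normalize_counts() expects a raw_counts matrix")
  }
  if (max(abs(counts - round(counts))) > 1e-8) {
    stop("raw counts must be integer-valued")
  }
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos) && !pseudo_reference) {
    stop("every gene contains a zero count; size factors are undefined. ",
         "Re-run with pseudo_reference = TRUE to use a positive-counts reference.")
  }
  if (any(all_pos)) {
    sub <- counts[all_pos, , drop = FALSE]
    logref <- rowMeans(log(sub))
    ratios <- exp(log(sub) - logref)
  } else {
    logref <- apply(counts, 1, function(v) mean(log(v[v > 0])))
    ratios <- exp(log(counts) - logref) # zeros give ratio 0, excluded below
    ratios[counts == 0] <- NA
  }
  sf <- apply(ratios, 2, stats::median, na.rm = TRUE)
  out <- log2(sweep(unclass(counts), 2, sf, "/") + 1)
  out <- expression_matrix(out, "normalized")
  attr(out, "size_factors") <- sf
  out
}

#' Restrict an expression matrix to genes of a metabolic model
#'
#' @param x expression matrix.
#' @param model a [metabolic_model()].
#' @return the matrix restricted to the row intersection, original row order
#'   preserved; retained/dropped counts are reported via `message()`.
#' @export
restrict_to_model_genes <- function(x, model) {
  stopifnot(inherits(model, "metabolic_model"))
  keep <- rownames(x) %in% model$genes
  if (!any(keep)) stop("no overlap between expression genes and model genes")
  message(sprintf("restrict_to_model_genes: retained %d of %d genes (%d model genes absent)",
                  sum(keep), nrow(x), length(model$genes) - sum(keep)))
  out <- x[keep, , drop = FALSE]
  attr(out, "expr_scale") <- expr_scale(x)
  out
}

#' Per-gene median absolute deviation
#'
#' Unscaled MAD (no 1.4826 consistency factor), the robust variability score
#' used to rank genes before clustering.
#'
#' @param x normalized expression matrix.
#' @return data.frame with columns `gene` and `mad`.
#' @export
mad_scores <- function(x) {
  md <- apply(x, 1, function(v) stats::median(abs(v - stats::median(v))))
  data.frame(gene = rownames(x), mad = unname(md), stringsAsFactors = FALSE)
}

#' Select the high-variability seed gene list
#'
#' Genes are sorted by MAD descending (ties broken by gene id), the first
#' `top_n` taken, and genes with MAD below `min_mad` then dropped.
#'
#' @param table data.frame from [mad_scores()].
#' @param top_n number of genes to take; default 1000.
#' @param min_mad MAD threshold applied after the top-n cut; default 0 (keep
#'   all). On variance-stabilized tumor data a threshold around 0.9 retains
#'   only strongly variable genes.
#' @return character vector of selected gene ids.
#' @export
select_seed_genes <- function(table, top_n = 1000, min_mad = 0) {
  stopifnot(top_n >= 1)
  if (!nrow(table)) stop("empty gene variability table")
  ord <- order(-table$mad, table$gene)
  top <- table[ord, ][seq_len(min(top_n, nrow(table))), , drop = FALSE]
  keep <- top$mad >= min_mad
  if (sum(keep) < top_n) {
    warning(sprintf("only %d of %d requested seed genes survive (min_mad = %g)",
                    sum(keep), top_n, min_mad))
  }
  top$gene[keep]
}
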