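# Shared internal helpers.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a child random seed from a master seed and a label
#'
#' All stochastic stages of the pipeline draw their seeds from a single master
#' seed through this function, so that one integer reproduces every output
#' without per-stage seed bookkeeping. The derivation is a fixed integer hash
#' of the label mixed with a Lehmer step of the master seed; results stay
#' within the 32-bit signed range R requires of `set.seed()`.
#'
#' @param seed integer master seed.
#' @param label character stage label (e.g. `"consensus"`, `"run3"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647 # 2^31 - 1, Mersenne prime used by the Lehmer generator
  code <- utf8ToInt(label)
  h <- 0
  for (i in seq_along(code)) h <- (h * 31 + code[i]) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% m)
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-invariant agreement between two clusterings, corrected for
#' chance; 1 for identical partitions, approximately 0 for independent ones.
#' Used to compare recovered subtype labels with planted truth.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (isTRUE(all.equal(maxi, expected))) return(1)
  (sij - expected) / (maxi - expected)
}

# Write a data.frame as the package's TSV dialect (tab-separated, UTF-8,
# no quoting, no row names).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
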