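# Non-negative matrix factorization X ~ WH by multiplicative updates.
#
# Three variants are provided:
#   brunet_kl     - Kullback-Leibler divergence objective (Brunet-style
#                   updates); the divergence D(X || WH) is guaranteed
#                   non-increasing under the updates.
#   lee_frobenius - squared Frobenius objective ||X - WH||^2 with the
#                   classical Lee-Seung updates, also monotone.
#   offset        - Frobenius model augmented with a shared nonnegative
#                   per-gene offset vector b, X ~ WH + b 1^T, updated
#                   multiplicatively; the offset absorbs expression common
#                   to all samples so W captures subtype-specific signal.

.nmf_eps <- 1e-12

kl_divergence <- function(X, WH) {
  pos <- X > 0
  sum(X[pos] * log(X[pos] / WH[pos])) - sum(X) + sum(WH)
}

#' Fit a non-negative matrix factorization
#'
#' @param X nonnegative numeric matrix (genes x samples).
#' @param r factorization rank, `0 < r < min(dim(X))`.
#' @param method one of `"brunet_kl"`, `"lee_frobenius"`, `"offset"`.
#' @param max_iter maximum number of update sweeps; default 2000.
#' @param tol stop when the relative objective change between sweeps falls
#'   below this; default `1e-6`. Use `0` to always run `max_iter` sweeps.
#' @param seed integer seed for the uniform-random nonnegative initialization.
#' @return an object of class `nmf_fit`: list with `W`, `H`, `offset` (or
#'   `NULL`), `rank`, `method`, `objective` (per-iteration trace), `seed`,
#'   `iterations`, `converged`.
#' @export
nmf_fit <- function(X, r, method = c("brunet_kl", "lee_frobenius", "offset"),
                    max_iter = 2000, tol = 1e-6, seed = 1) {
  method <- match.arg(method)
  X <- unclass(X)
  attributes(X)[setdiff(names(attributes(X)), c("dim", "dimnames"))] <- NULL
  if (any(X < 0)) stop("X has negative entries")
  m <- nrow(X); n <- ncol(X)
  if (r < 1 || r >= min(m, n)) stop("rank r out of range (need 0 < r < min(dim(X)))")

  set.seed(seed)
  sc <- sqrt(mean(X) / r)
  W <- matrix(stats::runif(m * r, min = 0.01, max = 1), m, r) * sc
  H <- matrix(stats::runif(r * n, min = 0.01, max = 1), r, n) * sc
  b <- if (method == "offset") stats::runif(m, 0.01, 1) * sc * 0.1 else NULL

  obj <- numeric(max_iter)
  iters <- max_iter
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (method == "brunet_kl") {
      V <- X / (W %*% H + .nmf_eps)
      H <- H * (crossprod(W, V)) / (colSums(W) + .nmf_eps)
      V <- X / (W %*% H + .nmf_eps)
      W <- W * tcrossprod(V, H) / rep(rowSums(H) + .nmf_eps, each = m)
      obj[it] <- kl_divergence(X, W %*% H + .nmf_eps)
    } else if (method == "lee_frobenius") {
      H <- H * crossprod(W, X) / (crossprod(W, W %*% H) + .nmf_eps)
      W <- W * tcrossprod(X, H) / (W %*% tcrossprod(H, H) + .nmf_eps)
      obj[it] <- sum((X - W %*% H)^2)
    } else {
      A <- W %*% H + b
      H <- H * crossprod(W, X) / (crossprod(W, A) + .nmf_eps)
      A <- W %*% H + b
      W <- W * tcrossprod(X, H) / (tcrossprod(A, H) + .nmf_eps)
      A <- W %*% H + b
      b <- b * rowSums(X) / (rowSums(A) + .nmf_eps)
      obj[it] <- sum((X - W %*% H - b)^2)
    }
    if (!is.finite(obj[it])) stop("non-finite objective at iteration ", it)
    if (it > 1) {
      rel <- abs(obj[it - 1] - obj[it]) / max(obj[it - 1], .nmf_eps)
      if (rel < tol) {
        iters <- it
        converged <- TRUE
        break
      }
    }
  }
  rownames(W) <- rownames(X)
  colnames(H) <- colnames(X)
  structure(
    list(W = W, H = H, offset = b, rank = r, method = method,
         objective = obj[seq_len(iters)], seed = seed,
         iterations = iters, converged = converged),
    class = "nmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit (%s): rank %d, %d x %d, %d iterations, objective %.6g\n",
              x$method, x$rank, nrow(x$W), ncol(x$H), x$iterations,
              x$objective[length(x$objective)]))
  invisible(x)
}

#' Relative reconstruction error of an NMF fit
#'
#' `||X - WH(-b)||_F / ||X||_F`.
#'
#' @param fit an `nmf_fit`.
#' @param X the matrix that was factorized.
#' @return numeric scalar.
#' @export
nmf_reconstruction_error <- function(fit, X) {
  R <- fit$W %*% fit$H
  if (!is.null(fit$offset)) R <- R + fit$offset
  sqrt(sum((unclass(X) - R)^2)) / sqrt(sum(unclass(X)^2))
}

#' Hard cluster labels from an NMF fit
#'
#' Sample `j` is assigned to the meta-profile with the largest coefficient in
#' column `j` of `H`; ties go to the smallest row index.
#'
#' @param fit an `nmf_fit`.
#' @return integer label vector (values `1..r`), named by sample.
#' @export
assign_labels <- function(fit) {
  stopifnot(inherits(fit, "nmf_fit"))
  lab <- apply(fit$H, 2, which.max)
  stats::setNames(as.integer(lab), colnames(fit$H))
}
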