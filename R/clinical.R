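# Association of subtype labels with survival and categorical clinical
# variables. Survival machinery (product-limit estimator, log-rank test, Cox
# partial likelihood with Breslow ties) is delegated to the survival package;
# exact and chi-square contingency tests to stats.

check_survival_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  if (any(records$time < 0)) stop("negative survival times")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  invisible(records)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator; censored times reduce the risk set without a
#' step.
#'
#' @param records data.frame with columns `time` and `event` (1 = event,
#'   0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `survival`
#'   (one row per distinct observed time).
#' @export
km_estimate <- function(records) {
  check_survival_records(records)
  if (!nrow(records)) stop("no records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Log-rank test for survival differences between groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance at
#' each distinct event time; the p-value comes from a chi-square distribution
#' with (number of groups - 1) degrees of freedom.
#'
#' @param records data.frame with columns `time`, `event` and `group`.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(records) {
  check_survival_records(records)
  if (length(unique(records$group)) < 2) stop("need at least two groups")
  if (sum(records$event) < 1) stop("no events; log-rank test undefined")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  df <- length(fit$n) - 1
  list(chisq = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Breslow tie handling; returns the coefficient,
#' hazard ratio, Wald 95% confidence interval and Wald p-value.
#'
#' @param records data.frame with columns `time` and `event`.
#' @param covariate numeric vector aligned with `records`, or the name of a
#'   column of `records`.
#' @return list with `beta`, `hr`, `ci` (length-2 vector), `p`, `se`,
#'   `converged`.
#' @export
cox_univariate <- function(records, covariate) {
  check_survival_records(records)
  x <- if (is.character(covariate) && length(covariate) == 1) {
    records[[covariate]]
  } else {
    covariate
  }
  if (is.null(x) || length(x) != nrow(records)) stop("covariate does not match records")
  if (length(unique(x)) < 2) stop("constant covariate")
  if (sum(records$event) < 1) stop("no events")
  dat <- data.frame(time = records$time, event = records$event, x = x)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = dat, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(beta = beta, hr = exp(beta),
       ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       p = 2 * stats::pnorm(-abs(beta / se)), se = se, converged = converged)
}

#' Univariate Cox screen of candidate prognostic genes
#'
#' Fits one univariate Cox model per gene on its expression and partitions
#' the significant genes by hazard-ratio direction: HR > 1 (high expression
#' associated with poor survival) versus HR < 1.
#'
#' @param x normalized expression matrix (genes x samples; column names are
#'   sample ids).
#' @param records survival data.frame with columns `sample`, `time`, `event`.
#' @param genes character vector of genes to screen.
#' @param alpha significance threshold; default 0.05.
#' @return list with `table` (per-gene beta, HR, CI, p), `worse` (genes with
#'   p < alpha and HR > 1), `better` (p < alpha, HR < 1), and `skipped`
#'   (genes absent from the matrix or with degenerate expression).
#' @export
prognostic_screen <- function(x, records, genes, alpha = 0.05) {
  check_survival_records(records)
  common <- intersect(colnames(x), records$sample)
  if (length(common) < 3) stop("too few samples shared between matrix and survival records")
  rec <- records[match(common, records$sample), , drop = FALSE]
  skipped <- setdiff(genes, rownames(x))
  genes <- intersect(genes, rownames(x))
  rows <- lapply(genes, function(g) {
    expr <- x[g, common]
    if (length(unique(expr)) < 2) return(NULL)
    fit <- cox_univariate(rec, unname(expr))
    data.frame(gene = g, beta = fit$beta, hr = fit$hr,
               ci_lower = fit$ci[1], ci_upper = fit$ci[2], p = fit$p,
               stringsAsFactors = FALSE)
  })
  degenerate <- genes[vapply(rows, is.null, TRUE)]
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(tab)) {
    tab <- data.frame(gene = character(0), beta = numeric(0), hr = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0), p = numeric(0))
  }
  rownames(tab) <- NULL
  list(table = tab,
       worse = tab$gene[tab$p < alpha & tab$hr > 1],
       better = tab$gene[tab$p < alpha & tab$hr < 1],
       skipped = c(skipped, degenerate))
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' Two-sided p by the "as or more extreme by probability" rule (the sum of
#' hypergeometric probabilities of tables no more probable than the observed
#' one). Larger tables are routed to a chi-square test with a warning.
#'
#' @param table integer matrix of counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts")
  if (!all(dim(table) == c(2, 2))) {
    warning("non-2x2 table; falling back to a chi-square test")
    return(unname(suppressWarnings(stats::chisq.test(table)$p.value)))
  }
  stats::fisher.test(table)$p.value
}

#' Cramer's V association strength
#'
#' `V = sqrt(chi^2 / (n (min(r, c) - 1)))` with the Pearson chi-square
#' statistic (no continuity correction). Values lie in `[0, 1]`: 0 for
#' independence, 1 for perfect association. Zero-marginal rows/columns are
#' dropped with a warning.
#'
#' @param table nonnegative count matrix.
#' @return numeric in `[0, 1]`.
#' @export
cramers_v <- function(table) {
  table <- as.matrix(table)
  n <- sum(table)
  if (n == 0) stop("empty contingency table")
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-marginal rows/columns")
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  if (min(dim(table)) < 2) return(0)
  chi2 <- unname(suppressWarnings(stats::chisq.test(table, correct = FALSE)$statistic))
  sqrt(chi2 / (n * (min(dim(table)) - 1)))
}

#' Dichotomize age at a cutoff
#'
#' Splits a numeric age vector into two categories (default `<50` / `>=50`)
#' for exact-test association with subtypes.
#'
#' @param age numeric vector.
#' @param cutoff split point; default 50.
#' @return factor with levels `"<cutoff"` and `">=cutoff"`.
#' @export
dichotomize_age <- function(age, cutoff = 50) {
  labs <- c(paste0("<", cutoff), paste0(">=", cutoff))
  factor(ifelse(age < cutoff, labs[1], labs[2]), levels = labs)
}
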