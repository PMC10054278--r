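# End-to-end orchestration: preprocess -> consensus clustering (rank sweep)
# -> differential expression -> reporter metabolites -> clinical association
# -> mutation profile, with a manifest recording every parameter, derived
# seed and input checksum so a run can be reproduced byte-identically.

default_pipeline_params <- function() {
  list(
    expression_scale = "raw_counts", # or "normalized" for external matrices
    top_n = 1000, min_mad = 0,
    ranks = 2:7, method = "offset", runs = 50, subsample_frac = 0.8,
    nmf_max_iter = 2000, nmf_tol = 1e-6,
    de_test = "welch_t", lfc_cut = 1, alpha = 0.05,
    min_k = 3, reporter_alpha = 0.05, n_sets = 100000,
    capture_size_mb = 38, min_freq = 10, mutation_alpha = 0.01,
    top_mutated = 20,
    seed = 1
  )
}

#' Build and validate a pipeline configuration
#'
#' @param expression path to a counts TSV (genes x samples) or an
#'   [expression_matrix()].
#' @param model path to a model TSV/SBML or a [metabolic_model()].
#' @param out_dir output directory (created if absent).
#' @param clinical optional path to a clinical TSV (columns `sample`,
#'   `time`, `event`, plus any of `stage`, `grade`, `histology`, `age`) or a
#'   data.frame.
#' @param maf optional path to a MAF or a `maf_table`.
#' @param de_table optional path to an external DE table (e.g. a
#'   tumor-versus-normal DESeq2 result) fed to a second reporter contrast.
#' @param ... parameter overrides; unknown keys are rejected. See
#'   `metsubtype:::default_pipeline_params()` for names and defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression, model, out_dir, clinical = NULL,
                            maf = NULL, de_table = NULL, ...) {
  params <- default_pipeline_params()
  extra <- list(...)
  unknown <- setdiff(names(extra), names(params))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  params[names(extra)] <- extra
  stopifnot(params$subsample_frac > 0, params$subsample_frac <= 1,
            params$alpha > 0, params$alpha < 1,
            params$reporter_alpha > 0, params$reporter_alpha < 1,
            params$min_k >= 1, params$runs >= 2)
  structure(c(list(expression = expression, model = model, out_dir = out_dir,
                   clinical = clinical, maf = maf, de_table = de_table),
              params),
            class = "pipeline_config")
}

input_checksums <- function(config) {
  paths <- Filter(function(p) is.character(p) && length(p) == 1 && file.exists(p),
                  config[c("expression", "model", "clinical", "maf", "de_table")])
  if (!length(paths)) return(list())
  as.list(tools::md5sum(unlist(paths)))
}

#' Run the metabolic-subtyping pipeline end to end
#'
#' Executes every stage for which inputs are configured, writes all tabular
#' outputs as TSV and reports as JSON under `config$out_dir`, and records a
#' `manifest.json` with parameters, derived stage seeds and input checksums.
#' A stage failure halts the run with the stage name; files written by the
#' failed stage are kept with a `.partial` suffix.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of in-memory stage results: `labels`,
#'   `rank_selection`, `de`, `degs`, `reporter`, `clinical`, `mutation`,
#'   `manifest`.
#' @export
run_subtype_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(...) file.path(config$out_dir, paste0(...))
  seeds <- list()
  stage_seed <- function(stage) {
    seeds[[stage]] <<- derive_seed(config$seed, stage)
    seeds[[stage]]
  }
  run_stage <- function(name, expr) {
    stage_files <- character(0)
    reg <- function(p) { stage_files <<- c(stage_files, p); p }
    tryCatch(
      eval(substitute(expr), envir = list2env(list(reg = reg), parent = parent.frame())),
      error = function(e) {
        for (p in stage_files) {
          if (file.exists(p)) file.rename(p, paste0(p, ".partial"))
        }
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  log_line <- function(...) message(sprintf(...))

  # -- load inputs ----------------------------------------------------------
  res <- run_stage("load", {
    x <- if (is.character(config$expression)) {
      read_expression_tsv(config$expression, scale = config$expression_scale)
    } else config$expression
    model <- if (is.character(config$model)) load_model(config$model) else config$model
    list(x = x, model = model)
  })
  x <- res$x; model <- res$model

  # -- preprocess -----------------------------------------------------------
  pre <- run_stage("preprocess", {
    if (identical(expr_scale(x), "raw_counts")) x <- normalize_counts(x)
    x <- suppressMessages(restrict_to_model_genes(x, model))
    seed_genes <- select_seed_genes(mad_scores(x), top_n = config$top_n,
                                    min_mad = config$min_mad)
    write_tsv(data.frame(gene = seed_genes), reg(outp("seed_genes.tsv")))
    log_line("preprocess: %d model genes in matrix, %d seed genes",
             nrow(x), length(seed_genes))
    list(x = x, seed_genes = seed_genes)
  })

  # -- consensus clustering -------------------------------------------------
  clu <- run_stage("cluster", {
    sel <- select_rank(pre$x[pre$seed_genes, , drop = FALSE],
                       ranks = config$ranks, method = config$method,
                       runs = config$runs, subsample_frac = config$subsample_frac,
                       seed = stage_seed("cluster"),
                       max_iter = config$nmf_max_iter, tol = config$nmf_tol)
    best <- sel$results[[as.character(sel$best_rank)]]
    labels <- stats::setNames(paste0("subtype", best$labels), names(best$labels))
    write_tsv(sel$metrics, reg(outp("rank_metrics.tsv")))
    write_tsv(data.frame(sample = names(labels), subtype = unname(labels)),
              reg(outp("subtype_labels.tsv")))
    cm <- data.frame(sample = rownames(best$C), best$C, check.names = FALSE)
    write_tsv(cm, reg(outp("consensus_matrix.tsv")))
    jsonlite::write_json(
      list(best_rank = sel$best_rank, metrics = sel$metrics),
      reg(outp("rank_selection.json")), auto_unbox = TRUE, digits = NA)
    log_line("cluster: best rank %d (cophenetic %.3f), sizes %s",
             sel$best_rank, best$cophenetic,
             paste(table(labels), collapse = "/"))
    list(selection = sel, best = best, labels = labels)
  })
  labels <- clu$labels

  # -- differential expression (subtype contrast) ---------------------------
  de <- run_stage("diffexp", {
    tab <- sort(table(labels), decreasing = TRUE)
    if (length(tab) > 2) {
      log_line("diffexp: %d clusters; contrasting the two largest (%s vs %s)",
               length(tab), names(tab)[1], names(tab)[2])
    }
    pair <- sort(names(tab)[1:2])
    keep <- labels %in% pair
    de_tab <- builtin_de_test(pre$x[, names(labels)[keep], drop = FALSE],
                              factor(labels[keep], levels = pair),
                              test = config$de_test)
    degs <- filter_degs(de_tab, lfc_cut = config$lfc_cut, alpha = config$alpha)
    write_tsv(de_tab, reg(outp("de_subtypes.tsv")))
    write_tsv(data.frame(gene = degs$up), reg(outp("degs_up.tsv")))
    write_tsv(data.frame(gene = degs$down), reg(outp("degs_down.tsv")))
    log_line("diffexp: %d up / %d down DEGs (%s vs %s)",
             length(degs$up), length(degs$down), pair[2], pair[1])
    list(table = de_tab, degs = degs, contrast = pair)
  })

  # -- reporter metabolites -------------------------------------------------
  rep_res <- run_stage("reporter", {
    graph <- build_bipartite_graph(model)
    contrasts <- list(subtype2 = de$table)
    if (!is.null(config$de_table)) {
      contrasts$tumor <- if (is.character(config$de_table)) {
        read_de_table(config$de_table)
      } else config$de_table
    }
    out <- list()
    for (cname in names(contrasts)) {
      for (mode in c("all", "up", "down")) {
        r <- reporter_metabolites(graph, contrasts[[cname]], mode = mode,
                                  min_k = config$min_k,
                                  alpha = config$reporter_alpha,
                                  n_sets = config$n_sets,
                                  seed = stage_seed(paste0("reporter_", cname, "_", mode)))
        write_tsv(r, reg(outp("reporter_", cname, "_", mode, ".tsv")))
        out[[paste0(cname, "_", mode)]] <- r
      }
    }
    log_line("reporter: %s", paste(names(out), vapply(out, nrow, 0L),
                                   sep = "=", collapse = ", "))
    out
  })

  # -- clinical associations ------------------------------------------------
  clin_res <- NULL
  if (!is.null(config$clinical)) {
    clin_res <- run_stage("clinical", {
      clin <- if (is.character(config$clinical)) read_tsv(config$clinical) else config$clinical
      clin <- clin[clin$sample %in% names(labels), , drop = FALSE]
      clin$group <- labels[clin$sample]
      report <- list(logrank = logrank_test(clin))
      km <- do.call(rbind, lapply(split(clin, clin$group), function(d) {
        cbind(group = d$group[1], km_estimate(d))
      }))
      write_tsv(km, reg(outp("km_curves.tsv")))
      assoc <- list()
      for (v in intersect(c("stage", "grade", "histology"), names(clin))) {
        tab <- table(clin$group, clin[[v]])
        assoc[[v]] <- list(fisher_p = fisher_exact(tab), cramers_v = cramers_v(tab))
      }
      if ("age" %in% names(clin)) {
        tab <- table(clin$group, dichotomize_age(clin$age))
        assoc$age <- list(fisher_p = fisher_exact(tab), cramers_v = cramers_v(tab))
      }
      report$associations <- assoc
      screen <- prognostic_screen(pre$x, clin,
                                  genes = unique(c(de$degs$up, de$degs$down)),
                                  alpha = config$alpha)
      write_tsv(screen$table, reg(outp("cox_screen.tsv")))
      report$prognostic <- list(worse = screen$worse, better = screen$better)
      jsonlite::write_json(report, reg(outp("clinical_report.json")),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      log_line("clinical: log-rank p = %.3g; %d prognostic genes (HR>1) / %d (HR<1)",
               report$logrank$p, length(screen$worse), length(screen$better))
      c(report, list(km = km, screen = screen))
    })
  } else log_line("clinical: no clinical table configured; stage skipped")

  # -- mutation profile -----------------------------------------------------
  mut_res <- NULL
  if (!is.null(config$maf)) {
    mut_res <- run_stage("mutation", {
      maf <- if (is.character(config$maf)) read_maf(config$maf) else config$maf
      lab_mut <- labels[labels %in% de$contrast]
      diff <- differential_mutation(maf, lab_mut, min_freq = config$min_freq,
                                    alpha = config$mutation_alpha)
      write_tsv(diff, reg(outp("mutation_diff.tsv")))
      burden <- do.call(rbind, lapply(sort(unique(unname(labels))), function(g) {
        b <- tmb(maf, names(labels)[labels == g],
                 capture_size_mb = config$capture_size_mb)
        data.frame(group = g, mean_tmb = b$mean_tmb,
                   n_samples = nrow(b$per_sample))
      }))
      write_tsv(burden, reg(outp("tmb.tsv")))
      co <- cooccurrence(maf, names(labels), top_n = config$top_mutated)
      write_tsv(co, reg(outp("cooccurrence.tsv")))
      log_line("mutation: %d genes tested, %d differential; TMB %s",
               nrow(diff), sum(diff$significant),
               paste(sprintf("%s=%.2f", burden$group, burden$mean_tmb), collapse = ", "))
      list(differential = diff, tmb = burden, cooccurrence = co)
    })
  } else log_line("mutation: no MAF configured; stage skipped")

  # -- manifest -------------------------------------------------------------
  manifest <- run_stage("manifest", {
    m <- list(
      package_version = as.character(utils::packageVersion("metsubtype")),
      parameters = config[names(default_pipeline_params())],
      stage_seeds = seeds,
      input_checksums = input_checksums(config),
      outputs = sort(setdiff(list.files(config$out_dir), "manifest.json"))
    )
    jsonlite::write_json(m, reg(outp("manifest.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  invisible(list(labels = labels, rank_selection = clu$selection,
                 de = de$table, degs = de$degs, reporter = rep_res,
                 clinical = clin_res, mutation = mut_res, manifest = manifest))
}

#' Simulate a complete pipeline-ready dataset directory
#'
#' Generates a coherent synthetic cohort: a toy metabolic model, a raw-count
#' expression matrix whose first rows are the model genes (so block structure
#' plants subtype-specific metabolic dysregulation), subtype-dependent
#' survival, clinical covariates with the association strengths typical of
#' tumor-subtype studies, and a MAF with differential and mutually exclusive
#' mutations. Everything is written as plain text plus a `truth.json` with
#' the planted ground truth.
#'
#' @param out_dir output directory.
#' @param n_samples cohort size; default 100.
#' @param n_genes total expression genes (at least the model gene count);
#'   default 400.
#' @param n_metabolites,genes_per_met toy model size; defaults 40 and 4.
#' @param separation,noise,dispersion see [make_expression()].
#' @param hazard_ratio subtype-2 hazard multiplier; default 2.
#' @param seed master seed.
#' @return (invisibly) list of file paths plus the `truth` list.
#' @export
simulate_dataset <- function(out_dir, n_samples = 100, n_genes = 400,
                             n_metabolites = 40, genes_per_met = 4,
                             separation = 4, noise = "nb", dispersion = 0.1,
                             hazard_ratio = 2, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tm <- make_toy_model(n_metabolites, genes_per_met, overlap = 0,
                       seed = derive_seed(seed, "model"))
  G <- length(tm$model$genes)
  if (n_genes < G) stop("n_genes must be at least the model gene count (", G, ")")

  # a quarter of metabolites is planted up (genes in subtype-2's block), a
  # quarter down, and the remaining half carries no subtype signal: their
  # genes map to shared (block-0) rows, so the cohort's DE landscape has the
  # mostly-null background that reporter scoring assumes
  mets <- vapply(tm$model$reactions, function(r) r$metabolites[1], "")
  n_up <- floor(n_metabolites / 4)
  n_down <- floor(n_metabolites / 4)
  planted_up_mets <- mets[seq_len(n_up)]
  planted_down_mets <- mets[n_up + seq_len(n_down)]
  bg_mets <- setdiff(mets, c(planted_up_mets, planted_down_mets))
  genes_of <- function(which_mets) {
    unique(unlist(lapply(tm$model$reactions[match(which_mets, mets)], `[[`, "genes")))
  }
  up_genes <- genes_of(planted_up_mets)
  down_genes <- genes_of(planted_down_mets)
  bg_genes <- genes_of(bg_mets)

  ex <- make_expression(n_genes = n_genes, n_samples = n_samples, r = 2,
                        separation = separation, noise = noise,
                        dispersion = dispersion,
                        shared_frac = length(bg_genes) / n_genes,
                        seed = derive_seed(seed, "expression"))
  block_of_row <- ex$truth$gene_block
  new_names <- rownames(ex$matrix)
  assign_rows <- function(genes, block) {
    free <- which(block_of_row == block)
    if (length(free) < length(genes)) {
      stop("not enough block-", block, " rows for the model genes")
    }
    new_names[free[seq_along(genes)]] <<- genes
  }
  assign_rows(down_genes, 1)
  assign_rows(up_genes, 2)
  assign_rows(bg_genes, 0)
  rownames(ex$matrix) <- new_names
  names(ex$truth$gene_block) <- new_names
  block_of <- ex$truth$gene_block
  labels <- ex$truth$labels

  surv <- make_survival(labels, hazard_ratio = hazard_ratio,
                        seed = derive_seed(seed, "survival"))
  set.seed(derive_seed(seed, "age"))
  clin <- data.frame(
    sample = surv$sample, time = surv$time, event = surv$event,
    stage = make_clinical(labels, 0.36, 4, seed = derive_seed(seed, "stage")),
    grade = make_clinical(labels, 0.58, 3, seed = derive_seed(seed, "grade")),
    histology = make_clinical(labels, 0.61, 4, seed = derive_seed(seed, "histology")),
    age = round(stats::rnorm(n_samples, 65, 10)),
    stringsAsFactors = FALSE
  )
  maf <- make_maf(labels,
                  planted_genes = data.frame(
                    gene = c("MUTD1", "MUTD2"),
                    freq_group1 = c(0.9, 0.1),
                    freq_group2 = c(0.3, 0.5)),
                  exclusive_pairs = list(c("EXA", "EXB")),
                  seed = derive_seed(seed, "maf"),
                  path = file.path(out_dir, "mutations.maf"))

  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    model = file.path(out_dir, "model.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    maf = file.path(out_dir, "mutations.maf"),
    truth = file.path(out_dir, "truth.json")
  )
  write_expression_tsv(ex$matrix, paths$counts)
  write_model_tsv(tm$model, paths$model)
  write_tsv(clin, paths$clinical)
  truth <- list(
    labels = as.list(stats::setNames(unname(labels), names(labels))),
    gene_block = as.list(stats::setNames(unname(block_of), names(block_of))),
    planted_up_mets = planted_up_mets,
    planted_down_mets = planted_down_mets,
    hazard_ratio = hazard_ratio,
    mutation = list(differential = c("MUTD1", "MUTD2"),
                    exclusive_pair = c("EXA", "EXB")),
    seed = seed
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth = truth)))
}
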