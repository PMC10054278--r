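# Genome-scale metabolic model ingestion and the enzyme-metabolite bipartite
# graph used for reporter-metabolite scoring.
#
# Metabolites are compartment-qualified throughout ("glycine[c]" etc.), so the
# same chemical species in different compartments is scored separately. Gene
# associations are flattened to plain gene sets: the reporter statistic
# aggregates per-gene z-scores, so AND/OR logic in gene-protein-reaction rules
# carries no extra information here.

#' Construct a metabolic model object
#'
#' @param reactions a list; each element a list with fields `id` (character),
#'   `genes` (character vector, may be empty) and `metabolites`
#'   (compartment-qualified character vector, e.g. `"m1[c]"`).
#' @return an object of class `metabolic_model` with components `genes`,
#'   `metabolites` and `reactions`.
#' @export
metabolic_model <- function(reactions) {
  stopifnot(is.list(reactions))
  ids <- vapply(reactions, function(r) r$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mets <- sort(unique(unlist(lapply(reactions, `[[`, "metabolites"))))
  genes <- sort(unique(unlist(lapply(reactions, `[[`, "genes"))))
  structure(
    list(genes = as.character(genes), metabolites = as.character(mets),
         reactions = reactions),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("Metabolic model: %d reactions, %d metabolites, %d genes\n",
              length(x$reactions), length(x$metabolites), length(x$genes)))
  invisible(x)
}

.compartment_re <- "\\[[^][]+\\]$"

strip_compartment <- function(x) sub(.compartment_re, "", x)

compartment_of <- function(x) {
  m <- regmatches(x, regexpr(.compartment_re, x))
  out <- rep(NA_character_, length(x))
  out[grepl(.compartment_re, x)] <- gsub("^\\[|\\]$", "", m)
  out
}

#' Load a genome-scale metabolic model
#'
#' Reads either the flat TSV dialect (columns `reaction_id`, `gene_ids`,
#' `metabolite_ids`; multi-valued cells joined with `";"`; metabolites
#' compartment-suffixed as `name[c]`) or an SBML Level 3 file with `fbc`
#' gene products.
#'
#' @param path path to the model file.
#' @param format `"tsv"` or `"sbml"`; default guessed from the file extension.
#' @return a [metabolic_model()] object.
#' @export
load_model <- function(path, format = c("auto", "tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tsv"
  }
  if (format == "tsv") load_model_tsv(path) else load_model_sbml(path)
}

split_cell <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

load_model_tsv <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  required <- c("reaction_id", "gene_ids", "metabolite_ids")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("model TSV is missing required columns: ", paste(missing, collapse = ", "))
  }
  reactions <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    mets <- split_cell(df$metabolite_ids[i])
    bad <- mets[!grepl(.compartment_re, mets)]
    if (length(bad)) {
      stop(sprintf("row %d: metabolite token(s) without compartment suffix: %s",
                   i, paste(bad, collapse = ", ")))
    }
    reactions[[i]] <- list(id = df$reaction_id[i],
                           genes = split_cell(df$gene_ids[i]),
                           metabolites = mets)
  }
  metabolic_model(reactions)
}

# SBML L3 + fbc reader; namespace-agnostic via local-name() so it tolerates
# prefix differences between model distributions.
load_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_comp <- xml2::xml_attr(sp, "compartment")
  met_label <- stats::setNames(paste0(sp_id, "[", sp_comp, "]"), sp_id)

  gp <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_id <- xml2::xml_attr(gp, "id")
  gp_label <- xml2::xml_attr(gp, "label")
  gp_label[is.na(gp_label) | !nzchar(gp_label)] <- gp_id[is.na(gp_label) | !nzchar(gp_label)]
  gene_label <- stats::setNames(gp_label, gp_id)

  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  reactions <- lapply(rx, function(r) {
    refs <- xml2::xml_find_all(r, ".//*[local-name()='speciesReference']")
    mets <- unique(xml2::xml_attr(refs, "species"))
    grefs <- xml2::xml_find_all(r, ".//*[local-name()='geneProductRef']")
    gids <- xml2::xml_attr(grefs, "geneProduct")
    genes <- unique(unname(gene_label[gids]))
    genes <- genes[!is.na(genes)]
    labs <- unname(met_label[mets])
    if (anyNA(labs)) {
      stop("reaction ", xml2::xml_attr(r, "id"),
           " references unknown species: ",
           paste(mets[is.na(labs)], collapse = ", "))
    }
    list(id = xml2::xml_attr(r, "id"), genes = genes, metabolites = labs)
  })
  metabolic_model(reactions)
}

#' Serialize a metabolic model to the flat TSV dialect
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  df <- data.frame(
    reaction_id = vapply(model$reactions, `[[`, "", "id"),
    gene_ids = vapply(model$reactions, function(r) paste(r$genes, collapse = ";"), ""),
    metabolite_ids = vapply(model$reactions, function(r) paste(r$metabolites, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Build the enzyme-metabolite bipartite graph
#'
#' An undirected edge links metabolite `m` to gene `g` whenever some reaction
#' contains both; duplicate memberships collapse to a single edge. Metabolites
#' in `excluded_metabolites` (matched either as compartment-qualified ids or
#' as bare names, in which case every compartment instance is dropped) are
#' removed before edge creation — typically used for currency metabolites
#' such as water or ATP.
#'
#' @param model a [metabolic_model()].
#' @param excluded_metabolites optional character vector of metabolite ids.
#' @return an undirected [igraph::igraph] bipartite graph; metabolite vertices
#'   have `type = FALSE`, gene vertices `type = TRUE`.
#' @export
build_bipartite_graph <- function(model, excluded_metabolites = character()) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  drop <- mets %in% excluded_metabolites |
    strip_compartment(mets) %in% excluded_metabolites
  mets <- mets[!drop]
  genes <- model$genes
  overlap <- intersect(mets, genes)
  if (length(overlap)) {
    stop("identifiers used both as gene and metabolite: ",
         paste(overlap, collapse = ", "))
  }
  edges <- lapply(model$reactions, function(r) {
    rm_ <- intersect(r$metabolites, mets)
    if (!length(rm_) || !length(r$genes)) return(NULL)
    cbind(rep(rm_, each = length(r$genes)), rep(r$genes, times = length(rm_)))
  })
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- unique(edges)
  }
  vdf <- data.frame(
    name = c(mets, genes),
    type = c(rep(FALSE, length(mets)), rep(TRUE, length(genes))),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = vdf
  )
}

#' Genes adjacent to a metabolite
#'
#' @param graph bipartite graph from [build_bipartite_graph()].
#' @param metabolite compartment-qualified metabolite id.
#' @return character vector of neighboring gene ids (possibly empty).
#' @export
metabolite_neighbors <- function(graph, metabolite) {
  vn <- igraph::V(graph)$name
  vt <- igraph::V(graph)$type
  if (!(metabolite %in% vn[!vt])) {
    stop("unknown metabolite: ", metabolite)
  }
  sort(names(igraph::neighbors(graph, metabolite)))
}

#' Metabolite vertices of the bipartite graph
#'
#' @param graph bipartite graph from [build_bipartite_graph()].
#' @return character vector of metabolite ids.
#' @export
graph_metabolites <- function(graph) {
  sort(igraph::V(graph)$name[!igraph::V(graph)$type])
}

#' Export the bipartite graph as a two-column edge TSV
#'
#' @param graph bipartite graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  # orient every edge metabolite -> gene for a stable serialization
  is_met <- !igraph::V(graph)$type[match(el[, 1], igraph::V(graph)$name)]
  el[!is_met, ] <- el[!is_met, c(2, 1)]
  df <- data.frame(metabolite = el[, 1], gene = el[, 2], stringsAsFactors = FALSE)
  df <- df[order(df$metabolite, df$gene), , drop = FALSE]
  write_tsv(df, path)
}
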