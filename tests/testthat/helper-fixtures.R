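# Shared fixtures, built in code at test time.

# Two-reaction toy model: R1 {A,B} x {m1[c], m2[c]}, R2 {B} x {m2[c], m3[m]}
toy_model <- function() {
  metabolic_model(list(
    list(id = "R1", genes = c("A", "B"), metabolites = c("m1[c]", "m2[c]")),
    list(id = "R2", genes = "B", metabolites = c("m2[c]", "m3[m]"))
  ))
}

write_toy_model_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "reaction_id\tgene_ids\tmetabolite_ids",
    "R1\tA;B\tm1[c];m2[c]",
    "R2\tB\tm2[c];m3[m]"
  ), path)
  path
}

# Minimal SBML L3 + fbc document with the same two-reaction structure.
write_toy_sbml <- function(path = tempfile(fileext = ".xml")) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '  <model id="toy">',
    '    <listOfSpecies>',
    '      <species id="m1" compartment="c"/>',
    '      <species id="m2" compartment="c"/>',
    '      <species id="m3" compartment="m"/>',
    '    </listOfSpecies>',
    '    <fbc:listOfGeneProducts>',
    '      <fbc:geneProduct fbc:id="gp_A" fbc:label="A"/>',
    '      <fbc:geneProduct fbc:id="gp_B" fbc:label="B"/>',
    '    </fbc:listOfGeneProducts>',
    '    <listOfReactions>',
    '      <reaction id="R1">',
    '        <listOfReactants><speciesReference species="m1"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="m2"/></listOfProducts>',
    '        <fbc:geneProductAssociation>',
    '          <fbc:or>',
    '            <fbc:geneProductRef fbc:geneProduct="gp_A"/>',
    '            <fbc:geneProductRef fbc:geneProduct="gp_B"/>',
    '          </fbc:or>',
    '        </fbc:geneProductAssociation>',
    '      </reaction>',
    '      <reaction id="R2">',
    '        <listOfReactants><speciesReference species="m2"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="m3"/></listOfProducts>',
    '        <fbc:geneProductAssociation>',
    '          <fbc:geneProductRef fbc:geneProduct="gp_B"/>',
    '        </fbc:geneProductAssociation>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'
  ), path)
  path
}

sorted_edges <- function(graph) {
  el <- igraph::as_edgelist(graph)
  el <- t(apply(el, 1, sort))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

# Independent brute-force mean silhouette on a distance matrix.
brute_silhouette <- function(d, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, which(labels == g)]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Independent brute-force reporter background: population moments of the
# prefactored aggregate over ALL k-subsets of the pool, by direct loop.
brute_background <- function(pool, k, prefactor = 1 / sqrt(k)) {
  sets <- utils::combn(length(pool), k)
  agg <- apply(sets, 2, function(ix) sum(pool[ix])) * prefactor
  mu <- mean(agg)
  list(mu = mu, sigma = sqrt(mean((agg - mu)^2)))
}

small_expression <- function(values, scale = "normalized") {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  expression_matrix(m, scale)
}
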