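Package: metsubtype
Title: Metabolic Subtype Discovery and Reporter Metabolite Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers metabolic subtypes of tumor cohorts by non-negative
    matrix factorization (NMF) consensus clustering of metabolic-gene
    expression, and characterizes them through reporter-metabolite inference
    on the enzyme-metabolite bipartite graph of a genome-scale metabolic
    model, differential expression, survival association (Kaplan-Meier,
    log-rank, univariate Cox), clinical-covariate association (Fisher's
    exact test, Cramer's V), and somatic-mutation statistics (tumor mutation
    burden, differential mutation, co-occurrence/mutual exclusivity).
    Includes synthetic-data generators with planted ground truth so the
    whole pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
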