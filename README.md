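# metsubtype

Metabolic subtype discovery and characterization for tumor transcriptomes.

Many cancers are metabolically heterogeneous: different patients rewire
different pathways, and the rewiring correlates with survival and genomic
alterations. `metsubtype` implements a complete, reproducible pipeline for
discovering such metabolic subtypes from bulk RNA-seq and characterizing
them at the network, clinical and genomic level:

1. **Preprocessing** — median-of-ratios library-size normalization with a
   `log2(x + 1)` transform, restriction of the expression matrix to the
   genes of a genome-scale metabolic model (GEM), and selection of a
   high-variability seed gene list by median absolute deviation (MAD).
2. **NMF consensus clustering** — non-negative matrix factorization
   `X ≈ WH` (Kullback–Leibler, Frobenius, or offset variants, all with
   multiplicative updates) repeated over random subsamples of the cohort.
   The consensus matrix `C` records how often each sample pair co-clusters;
   the cophenetic correlation coefficient, dispersion `mean(4(c − ½)²)` and
   mean silhouette width of `1 − C` select the number of subtypes.
3. **Differential expression** — a transparent built-in two-group test
   (Welch t or Wilcoxon on the normalized scale, Benjamini–Hochberg
   adjusted), or external DESeq2/limma tables ingested verbatim; DEGs are
   called at `|log2FC| > 1` and adjusted `p < 0.05`.
4. **Reporter metabolites** — the core network statistic. Each gene's
   p-value becomes a normal deviate `z = Φ⁻¹(1 − p)`; a metabolite with `k`
   scored neighbor genes in the enzyme–metabolite bipartite graph of the
   GEM gets the aggregate
   `Z_met = (1/√k) Σ zᵢ`, which is corrected against 100,000 random
   size-`k` gene sets: `Z_corr = (Z_met − μₖ)/σₖ` (enumerated exhaustively
   when there are fewer than 100,000 distinct sets). Metabolites with at
   least 3 scored neighbors and reporter `p < 0.05` are called significant,
   separately for all / upregulated / downregulated gene sets.
5. **Clinical association** — Kaplan–Meier curves, log-rank tests, a
   univariate Cox screen of DEGs split by hazard-ratio direction, Fisher's
   exact test and Cramer's V for categorical covariates.
6. **Mutation profile** — per-gene mutation frequency, tumor mutation
   burden per megabase, differential mutation between subtypes (Fisher,
   minimum total frequency 10, `p < 0.01`), and pairwise
   co-occurrence/mutual-exclusivity of the most frequently mutated genes.

A synthetic-data module generates cohorts with planted subtypes, planted
dysregulated metabolite neighborhoods, subtype-dependent survival,
clinical covariates with a target Cramer's V, and planted mutation
structure, so the entire pipeline is testable end to end with no external
downloads.

## Input formats

* **Expression** — TSV, genes × samples, first column gene ids, header
  row sample ids; raw integer counts or externally normalized values.
* **Metabolic model** — SBML Level 3 with `fbc` gene products, or a flat
  TSV with columns `reaction_id`, `gene_ids`, `metabolite_ids`
  (multi-valued cells joined with `;`, metabolites compartment-suffixed,
  e.g. `glycine[c]`; UTF-8, tab-separated).
* **Clinical** — TSV with `sample`, `time`, `event` plus optional
  `stage`, `grade`, `histology`, `age`.
* **Mutations** — MAF (GDC dialect) with `Hugo_Symbol`,
  `Tumor_Sample_Barcode`, `Variant_Classification`.

## Worked example

```r
library(metsubtype)

dir <- "demo"
simulate_dataset(dir, n_samples = 60, seed = 42)

cfg <- pipeline_config(
  expression = file.path(dir, "counts.tsv"),
  model      = file.path(dir, "model.tsv"),
  out_dir    = file.path(dir, "results"),
  clinical   = file.path(dir, "clinical.tsv"),
  maf        = file.path(dir, "mutations.maf"),
  ranks = 2:4, runs = 20, top_n = 200, seed = 42
)
res <- run_subtype_pipeline(cfg)
```

The run logs one line per stage:

```
preprocess: 160 model genes in matrix, 160 seed genes
cluster: best rank 2 (cophenetic 1.000), sizes 30/30
diffexp: 40 up / 40 down DEGs (subtype2 vs subtype1)
reporter: subtype2_all=20, subtype2_up=10, subtype2_down=0
clinical: log-rank p = 0.00253; 39 prognostic genes (HR>1) / 40 (HR<1)
mutation: 5 genes tested, 1 differential; TMB subtype1=0.11, subtype2=0.09
```

The rank sweep shows why two subtypes are selected — consensus clustering
is perfectly stable at rank 2 and degrades above it:

```r
res$rank_selection$metrics
#>   rank cophenetic dispersion silhouette
#> 1    2  1.0000000  1.0000000  1.0000000
#> 2    3  0.9959181  0.8599713  0.8228722
#> 3    4  0.9901648  0.7446954  0.5325295
```

And the top reporter metabolites are the planted dysregulated
neighborhoods (`k` scored neighbor genes, raw and background-corrected
aggregate z, reporter p-value):

```r
head(res$reporter$subtype2_all, 3)
#>   metabolite compartment k    z_raw     mu_k  sigma_k z_corrected    p_value
#> 1  met001[c]           c 4 15.88269 8.947019 3.524381    1.967912 0.02453908
#> 2  met002[m]           m 4 15.88269 8.947019 3.524381    1.967912 0.02453908
#> 3  met003[n]           n 4 15.88269 8.947019 3.524381    1.967912 0.02453908
```

All outputs (subtype labels, consensus matrix, rank metrics, DE tables,
reporter tables per direction, KM coordinates, Cox screen, mutation
tables) are written to `out_dir` as TSV/JSON, together with a
`manifest.json` recording every parameter, derived stage seed and input
checksum; re-running with the same seed reproduces every file
byte-identically.

A thin command-line wrapper with `simulate` and `run-all` subcommands is
installed at `inst/cli/metsubtype.R`.

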