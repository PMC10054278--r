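---
title: "Metabolic subtyping and reporter metabolites: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic subtyping and reporter metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsubtype)
```

This vignette explains the statistical machinery behind `metsubtype`: the
models each stage assumes, the parameters that matter and their defaults,
the numerical choices, and what the synthetic-data validation does and does
not establish about real cohorts.

## The enzyme–metabolite graph

A genome-scale metabolic model is reduced to an undirected bipartite graph:
metabolite nodes (compartment-qualified, so cytosolic and mitochondrial
pools of the same compound are distinct) and gene nodes, with an edge
whenever a reaction contains both. Two deliberate simplifications:

* **Gene-association flattening.** Boolean AND/OR structure in
  gene–protein–reaction rules is flattened to the plain gene set. The
  reporter statistic aggregates per-gene evidence; isozyme/complex logic
  has no representation in a per-gene z-score and pretending otherwise
  would be false precision. Genes (not transcripts or proteins) are the
  enzyme nodes because differential-expression statistics are per-gene.
* **No default currency-metabolite exclusion.** Water, ATP and protons
  connect large swaths of the network and some users will want them gone,
  but removal changes the statistic's input, so it is opt-in
  (`excluded_metabolites`), matched per compartment or by bare name.

## NMF consensus clustering

The seed-gene expression matrix `X` (genes × samples, nonnegative) is
factorized as `X ≈ WH` with rank `r` equal to the number of candidate
subtypes. Three multiplicative-update variants are provided: the
Kullback–Leibler objective (`brunet_kl`), the squared Frobenius objective
(`lee_frobenius`), and an `offset` variant `X ≈ WH + b·1ᵀ` whose
per-gene offset absorbs expression common to all samples so the factors
capture subtype-specific signal. KL and Frobenius updates provably never
increase their objective; the tests assert this per iteration at a 1e-9
slack. Initialization is uniform-random nonnegative, scaled to the data
mean, from an explicit seed; a denominator floor of 1e-12 guards the
updates against division by zero. Iteration stops at `max_iter` (default
2000) or when the relative objective change drops below `tol` (default
1e-6; use 0 to disable early stopping, e.g. when tracing convergence).

Single NMF runs on subsampled cohorts vote into a consensus matrix:
`C[i, j]` is the fraction of runs, among those where samples `i` and `j`
were co-sampled, in which they received the same label (the label of a
sample is its dominant meta-profile, ties to the smaller index). Defaults:
50 runs, subsample fraction 0.8 — the fraction is a common
consensus-clustering convention, not something the method is sensitive to;
at these defaults a never-co-sampled pair is vanishingly rare (such pairs
get `C = 0` and a warning). Final subtype labels come from average-linkage
hierarchical clustering of `1 − C` cut at `r`, not from any single run.

Rank selection sweeps `r = 2..7` and maximizes the cophenetic correlation
coefficient (correlation between the consensus distances and their
dendrogram's cophenetic distances), breaking exact ties by higher mean
silhouette width and then by the smaller rank — preferring the simpler
model when stability cannot distinguish candidates. Dispersion
`mean(4(c − ½)²)` is reported alongside. All three metrics equal exactly 1
on a perfectly reproducible clustering, which the noiseless planted-data
tests confirm.

## Differential expression

The built-in test is deliberately plain: per gene, `log2FC` is the
difference of group means on the log2 scale (second factor level minus
first), p-values from a Welch t-test (default) or Wilcoxon rank-sum test,
Benjamini–Hochberg adjustment across genes. Genes constant in both groups
get `p = 1` with a `constant` flag rather than an error. This is a
stand-in, not a reimplementation of count-model inference: negative
binomial engines such as DESeq2 model dispersion and shrinkage that a
two-sample test does not, so externally computed tables are first-class
inputs (`read_de_table()`, DESeq2 column names as default aliases, BH
recomputed with a warning when the adjusted column is absent). DEG calls
use strict inequalities, `log2FC > 1` (or `< −1`) and adjusted `p < 0.05`,
so boundary values are excluded.

## The reporter-metabolite statistic

Gene p-values are mapped to normal deviates `z = Φ⁻¹(1 − p)` after
clamping `p` into `[1e-15, 1 − 1e-15]`; the clamp keeps numerically-zero
p-values finite (z ≈ 7.94) without materially changing any ranking. For a
metabolite with `k` neighbors present in the score table,

&nbsp;&nbsp;`Z_raw = (1/√k) · Σ zᵢ`.

**Prefactor.** With `1/√k`, `Z_raw` is itself standard normal under
independent standard-normal neighbor scores. A `1/k` average is the other
natural reading. The background correction standardizes by the mean and
standard deviation of the same aggregate over random gene sets, so any
size-dependent prefactor cancels algebraically — the tests verify the two
choices give identical corrected scores to 1e-12 across random networks.
The choice is therefore cosmetic; `1/√k` is the default.

**Background.** `μₖ` and `σₖ` are the moments of the aggregate over
random size-`k` subsets of the score pool: 100,000 sampled sets by
default, or exhaustive enumeration of all `C(N, k)` subsets whenever that
is at most `n_sets` (exact moments, population variance). One background
per distinct `k` is computed and cached, with its seed derived from the
master seed and `k` alone, so results are independent of metabolite
iteration order and byte-reproducible. The default pool is every scored
gene; `background = "graph_only"` restricts it to graph members for users
who consider non-network genes an unfair reference.

**Directional runs.** The up (down) analysis restricts the score table —
neighborhoods *and* background pool — to genes with positive (negative)
fold change before scoring. The alternative, assigning `p = 1` to
wrong-direction genes, floods the aggregate with clamped minimal z-values
and makes `k` incomparable across metabolites; restriction is the cleaner
reading of running the analysis "with upregulated genes". Consequently
`k` counts same-direction scored neighbors, and the significance filters —
at least `min_k = 3` scored neighbors and reporter `p < 0.05` — apply to
that count.

**Degenerate cases.** A metabolite with no scored neighbors is skipped
and listed; a constant score pool, or a pool whose every subset aggregates
identically (`σₖ = 0`, e.g. `k = N`), flags the metabolite instead of
producing an infinite score.

## Survival and clinical association

Kaplan–Meier estimation, the log-rank test and univariate Cox regression
are delegated to the `survival` package; Cox models use Breslow tie
handling (the simplest consistent choice; with continuous expression
covariates ties are rare and the choice is immaterial). The prognostic
screen fits one univariate model per DEG and partitions significant genes
by hazard-ratio direction. Fisher's exact test handles 2×2 tables (ages
are dichotomized at 50 for this purpose); larger tables fall back to a
chi-square test with a warning rather than guessing at an exact-network
implementation. Cramer's V is implemented in its standard form
`V = √(χ²/(n·(min(r,c)−1)))`, which lies in `[0, 1]` by construction —
descriptions of V ranging to −1 trace to a confusion with the 2×2 phi
coefficient and are not reproducible from the formula.

## Mutation statistics

Only the non-synonymous MAF classes are counted. Mutation frequency
deduplicates per sample. TMB divides non-synonymous counts by a
configurable capture size, default 38 Mb — a common whole-exome
convention; published per-Mb figures rarely state their denominator, so it
is a parameter, and an `"all"` variants switch is provided. Differential
mutation tests genes with at least 10 mutated samples overall (2×2
Fisher, `p < 0.01`); co-occurrence tests the top 20 most frequent genes
pairwise, labeling odds ratio > 1 co-occurring, < 1 mutually exclusive,
and exactly 1 `"none"` (an undefined boundary some tools silently fold
into one side); identical mutation sets report an infinite odds ratio.
Raw p-values drive the calls, with a BH column reported alongside.

## Synthetic data: what it emulates, and what it does not

The generators produce the statistical structure each stage assumes, with
the truth recorded:

* `make_expression()` — rank-`r` block expression. Each subtype owns a
  contiguous gene block elevated by `separation` (default 4, a strongly
  separated regime in which consensus clustering should be near-perfectly
  stable) over a ~0.1 background loading; an optional `shared_frac` of
  genes is elevated in every rank, emulating expressed-but-not-differential
  genes. Counts are negative binomial with dispersion 0.1 (typical bulk
  RNA-seq overdispersion); Poisson and noiseless variants support clean
  tests.
* `make_toy_model()` — one reaction per metabolite, gene sets
  interpolating between fully private (`overlap = 0`) and a shared pool
  (`overlap = 1`), compartments round-robin over `{c, m, n}`.
* `make_de_scores()` — planted neighborhoods get one-sided p-values from
  `z ~ N(effect, 1)` with `effect = 3` by default; all other genes are
  uniform, giving exact null calibration checks.
* `make_survival()` — exponential times with a planted hazard ratio
  (default 2) and independent uniform censoring to a target fraction
  (default 0.2).
* `make_clinical()` — a mixture of a deterministic subtype→category map
  (weight `w`) and uniform noise; `w` is solved by bisection so the
  population Cramer's V of the implied table equals the target (defaults
  in `simulate_dataset()`: 0.36 stage, 0.58 grade, 0.61 histology —
  moderate-to-strong associations typical of tumor-subtype cohorts).
* `make_maf()` — group-specific Bernoulli mutation, a flat background
  rate, and exclusive pairs drawn from disjoint cohort halves.

`simulate_dataset()` assembles a coherent cohort: a quarter of metabolites
planted up, a quarter down, and the rest mapped onto shared expression
rows — without that mostly-null background every metabolic gene would be
differential and the background correction would (correctly) find nothing
exceptional, which is not the regime reporter analysis targets.

What passing these tests shows: the algorithms are correctly implemented,
calibrated under their nulls, and powered for effects of the planted
magnitude at the tested cohort sizes. What it does not show: robustness to
batch effects, tumor purity, histology-specific programs, GC/length
biases, or subtype structure that is not low-rank — real-data behavior
still depends on upstream normalization and model curation quality.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run on deliberately small
instances — cohorts of 40–100 samples, models of 15–40 metabolites,
consensus sweeps with 6–20 runs — chosen so the complete validation suite
executes in a few minutes on one core while leaving every statistical
check well-powered (the planted effects are strong enough that the pass
thresholds sit far from the decision boundary). All stochastic stages
draw their seeds deterministically from one master seed via a labeled
hash (`derive_seed()`), so any run — including the full pipeline with its
manifest — is reproducible byte for byte.

## Known limitations

* The built-in DE test ignores count dispersion; use external tables for
  publication-grade inference.
* Flux-based scoring, reporter reactions/subnetworks, copy-number
  analysis and figure rendering are out of scope.
* The r×c exact test is approximated by chi-square.
* nsNMF and sparse/semi-supervised NMF variants are not implemented; the
  method registry accepts additions.
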