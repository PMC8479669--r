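---
title: "Secondary co-expression networks and gene multifunctionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary co-expression networks and gene multifunctionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmsca)
```

## The model

Bulk-tissue expression mixes the transcriptional programs of every cell
type in the sample. `gmsca` works from an additive model of a gene's
expression across samples,

$$ e \;=\; \sum_{c \in CT} \alpha_c x_c \;+\; \beta x_0 , $$

where $x_c$ is the per-sample contribution of cell type $c$, $\alpha_c$
the gene's loading on that cell type, and $x_0$ collects everything else
(shared regulation, technical structure). A gene with two non-trivial
loadings is *multifunctional*: its expression carries two cell-type
contexts, but a co-expression network can only place it in one module —
the one matching its dominant loading.

The package's strategy is to *subtract* the dominant context and look
again. For every module enriched for a cell type, the first principal
component of the module's expression is taken as that cell type's
contribution $x_c$ (it is the dominant shared signal of a module defined
by that cell type's markers). The module is reconstructed without it, a
full secondary network is rebuilt, and genes whose secondary module is
enriched for a *different* cell type are classified multifunctional.

## Pipeline stages and their parameters

**Residualization.** Sample covariates (age, sex, RIN, PMI, ...) are
regressed out of every gene by OLS before network construction; networks
are built from residuals. Categorical covariates are expanded to
treatment-coded indicators. Batch correction and surrogate variables are
out of scope — matrices are expected to arrive pre-corrected.

**Soft power** (`fit_threshold = 0.80`, grid 1–30). The smallest power
whose connectivity histogram fits a power law with signed $R^2 \ge 0.80$
(10 equal-width connectivity bins, regression of $\log_{10}$ frequency on
$\log_{10}$ mean connectivity). When no power qualifies, the best-fitting
power is used with a warning. A caveat worth knowing: at strong powers
even i.i.d. noise can pass this conventional fit, so the threshold is a
guard against *under*-thresholding, not a test of network quality.

**TOM and clustering** (`min_module_size = 100`). Standard unsigned
topological overlap; unsigned adjacency is the default (signed-hybrid is a
config option). Average-linkage clustering of $1 - \mathrm{TOM}$ is cut at
the merge height yielding the most clusters of at least 100 genes. Ties
are broken toward the *lower* height. This choice is deliberate: a tied
low cut can leave the tail of a module unassigned, which the refinement
step reattaches, whereas a tied high cut can merge two distinct cell-type
modules — and no later stage can split a merged module. We observed
exactly this failure mode (neuron and astrocyte modules merging, then
mass-misclassification of one module as multifunctional) before settling
on the low tie-break.

**k-means refinement** (`max_kmeans_iter = 50`, `reassign_floor = 0.3`).
Centroids are module eigengenes; each iteration reassigns every gene to
the module whose eigengene it best correlates with in absolute value,
provided the correlation reaches 0.3 — genes below the floor become
unassigned, which keeps diffuse background genes from inflating modules.
The floor is a tool decision, configurable. Note that this refinement has
no monotone objective guarantee (centroids move after each pass); in
practice it converges in a handful of iterations and we test convergence
to a fixed point rather than per-iteration monotonicity.

**Cell-type enrichment** (`alpha = 0.05`). One-sided Fisher exact tests of
every module against every marker set, Bonferroni over all tests in the
table, then an OLS regression of $-\log_{10} p$ on module size whose
residual must be positive for a call — large modules overlap every gene
set, and the regression removes that artifact. A module passing for
several cell types keeps only the most significant one (the marginal
signal is dropped). Two numerical details: p-values are floored at
1e-300 before the log, and "positive residual" means greater than 1e-10,
so exact size artifacts cannot sneak in on round-off. With fewer than
three tests the size adjustment is skipped (with a warning); with no size
variation an intercept-only fit centers the values, preserving the
p-value ranking.

**Signal removal** (`variance_target = 0.90`, `tail = "drop"`). Gene rows
are centered (not scaled — the reconstruction must return to expression
units), the SVD is taken, and $k$ is the smallest component count with
cumulative explained variance at least 90%. Reconstruction uses
components $2..k$: the first component (the cell-type signal) and the
noise tail beyond 90% are both discarded. The alternative reading —
keep all components but the first — is available as `tail = "keep"`.
A rank-1 module (k = 1) collapses to its gene means with a warning; its
genes are inert in the secondary network. By construction the corrected
matrix's leading component is exactly the original second component, a
property the test suite checks; note that the corrected first-PC
*share* is therefore always at least the original second component's
share, never below it.

**Secondary networks.** One per enriched cell type, built on the full
corrected gene pool. The soft power is re-selected per corrected matrix
(the correlation structure changes materially after removal);
`reuse_power = TRUE` is available.

**Classification.** The transition state is a total function of the
(primary cell type, secondary cell type) pair: activated (none → some),
deactivated (some → none), multifunctional (different types),
strongly typed (same type), strongly non-typed (none → none). Aggregation
over all secondary networks is additive: a gene's cell types are the
union of its assignments, and the annotation gain is
$(\mathrm{typed}_{after} - \mathrm{typed}_{PGCN}) / \mathrm{pool}$.

## The synthetic generator

`simulate_bulk()` draws independent standard-normal latent vectors per
cell type plus a shared $x_0$, and generates module genes as
$\alpha_g x_c + \beta_g x_0 + \varepsilon$ with folded-normal loadings.
Defaults: 4 cell types with 300-gene modules (60 designated markers
each), 40 dual-loading genes for each of the two disjoint cell-type pairs
(loadings 1.0 primary / 0.6 secondary), 800 background genes, 150
samples, $\beta_g \sim |N(0.5, 0.1)|$ and noise SD 1. This regime gives
within-module correlations around 0.55, between-module around 0.1, and
background–eigengene correlations safely under the 0.3 reassignment
floor — i.e. a clearly solvable but non-trivial instance of the additive
model. Multifunctional genes sit in their primary type's module, so the
primary network sees one context and the secondary reveals the other.

What the generator does *not* emulate: count noise (negative binomial),
library-size and compositional effects, correlated cell-type proportions
across samples, batch structure, or marker sets with errors. Passing
tests on this fixture therefore demonstrate the machinery's correctness
under the additive model, not robustness to real RNA-seq artifacts.

```{r, eval = FALSE}
sim <- simulate_bulk(seed = 1)
res <- run_gmsca(default_config(expression = sim$expr,
                                markers = sim$truth_markers, seed = 1))
evaluate_recovery(res$pgcn, sim,
                  mapping = res$pgcn_enrichment$mapping,
                  states = res$states)
```

## Validation statistics

**Preservation Z-summary.** Density (mean absolute intramodular
correlation in the test data) and connectivity (Spearman correlation of
intramodular connectivity between reference and test) are each z-scored
against a permutation null of random same-size gene sets; their mean is
the Z-summary, read against the conventional thresholds (2: weak, 10:
strong preservation). This is a deliberate two-statistic simplification
of the full WGCNA preservation battery — it preserves the thresholds'
semantics on synthetic data but is not numerically identical to
WGCNA's statistic. Permutation seeds are explicit arguments.

**Specificity matrices.** For sorted-cell (immunopanning-style) profiles,
replicates are averaged, the matrix is log2(x+1)-transformed and then
standardized as a whole; entries above the global mean are specific. (Log
first, then scale: the log stabilizes the variance; the order is
configurable in spirit but fixed here.) For single-cell counts, all-zero
cells are dropped and an entry is specific when the cell-type mean is at
least 3x the gene's overall mean — "overall" resolved as the per-gene
mean across all retained cells, since a per-gene-and-cell-type overall
mean would make the criterion self-referential. Genes with zero overall
mean are never specific.

**Bootstrap enrichment** compares a gene list's mean specificity with
random same-size lists, $p = (1 + \#\{null \ge obs\}) / (n_{boot} + 1)$,
which is exact-valued in $(0, 1]$ and uniform under the null at the grid
resolution. **Overlap tests** remove known markers from predictions,
reference and background before the Fisher test, so marker genes cannot
flatter the agreement. **Phenotype enrichment** reports per-term module
coverage (threshold 2%) and fold change over the background rate.

## Problem sizes and determinism

The test suite and the acceptance script run the full default synthetic
scale (2080 genes x 150 samples; a complete pipeline run takes on the
order of a minute on one core) and reduced configurations (two or three
80-gene modules, 60 samples) for unit-level properties. Network
construction is fully deterministic given the input matrix and
parameters; simulation and permutation procedures take explicit integer
seeds, and a pipeline run with a fixed config and seed reproduces its
manifest byte for byte. Degenerate inputs are handled explicitly:
constant genes are dropped with a warning before correlation work,
rank-deficient covariate designs and sub-minimum module sizes are hard
errors, and empty enrichment mappings short-circuit to empty (but valid)
result tables.

## Known limitations

- The additive model attributes a module's entire first principal
  component to one cell type; correlated latent factors or a dominant
  technical axis would be removed instead.
- Modules that merge two cell types' genes before refinement can shadow
  true multifunctionality (mitigated, not eliminated, by the low
  tie-break and refinement).
- The scale-free fit criterion is permissive at strong powers (see
  above); inspect the per-power fits (attribute `"fit"` of
  `select_soft_power()`) when in doubt.
- Marker sets are trusted as given; no cross-species mapping is computed
  (homolog tables are plain user-supplied inputs).
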