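# gmsca

Gene multifunctionality analysis with secondary co-expression networks.

## The problem

Weighted gene co-expression network analysis of bulk-tissue transcriptomes
groups genes into modules, and modules enriched for cell-type marker genes
let every member gene inherit a `<gene, cell type, function>` annotation by
guilt-by-association. Because modules partition the gene pool, this yields
at most **one** cell type and function set per gene — yet many genes act in
several cell types (SNCA or TP53 are classic examples). In heterogeneous
tissue such as brain, a gene's strongest co-expression signal (say, its
neuronal context) masks any weaker signal from a second cell type.

`gmsca` implements a secondary-network strategy for uncovering those masked
contexts from bulk data alone:

1. Build a **primary network** (PGCN): soft-threshold power selected for
   scale-free topology, adjacency `a_ij = |cor(x_i, x_j)|^β`, topological
   overlap matrix `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   average-linkage clustering of `1 − TOM` with a 100-gene minimum module
   size, then k-means-style refinement of module memberships against module
   eigengenes (first principal components).
2. **Annotate modules with cell types** by one-sided Fisher exact tests
   against marker gene sets, Bonferroni-corrected, with a regression-based
   correction for the module-size effect on `−log10 p`, keeping a single
   cell type per module.
3. **Remove each cell type's signal**: under the additive model
   `e = Σ_c α_c x_c + β x_0`, the first principal component of a
   cell-type-enriched module is that cell type's per-sample contribution.
   Each such module is reconstructed from components `2..k` (with `k` the
   smallest count explaining 90% of variance) and a **secondary network**
   (SGCN) is built per cell type from the corrected full matrix.
4. **Classify transitions** per gene between PGCN and each SGCN:
   `activated`, `deactivated`, `multifunctional` (different cell type in
   the SGCN), `strongly_typed`, `strongly_non_typed`; aggregate triplets
   and per-gene annotations over all secondary networks.

Validation statistics (permutation Z-summary for module preservation,
boolean cell-type specificity matrices from sorted-cell or single-cell
references, overlap tests with marker exclusion, bootstrap specificity
enrichment, phenotype-term coverage/fold-change) and a synthetic
bulk-expression generator with planted ground truth are included.

## Worked example

```r
library(gmsca)

sim <- simulate_bulk(seed = 1)      # 2080 genes x 150 samples, 4 cell types
res <- run_gmsca(default_config(
  expression = sim$expr, markers = sim$truth_markers, seed = 1))

res$pgcn
#> coexpression_network (primary)
#>   genes: 2080  modules: 5  unassigned: 35
#>   soft power: 14

res$pgcn_enrichment$mapping
#>                M1                M2                M3                M4
#>          "neuron"       "microglia"       "astrocyte" "oligodendrocyte"

round(res$summary[c("typed_pgcn", "multifunctional_any", "deactivated_any")], 3)
#>          typed_pgcn multifunctional_any     deactivated_any
#>               0.617               0.038               0.578

ev <- evaluate_recovery(res$pgcn, sim,
                        mapping = res$pgcn_enrichment$mapping,
                        states = res$states)
round(unlist(ev[c("ari_all", "multifunctional_sensitivity",
                  "false_multifunctional_rate")]), 3)
#>                     ari_all multifunctional_sensitivity
#>                       0.961                       0.912
#>  false_multifunctional_rate
#>                       0.006
```

The network recovers the planted modules (adjusted Rand index 0.96), each
planted cell type maps to exactly one enriched module, and 91% of the
planted dual-loading genes are re-discovered as multifunctional toward
their second cell type, with a 0.6% false-positive rate among pure
single-type genes.

A command-line front end over the same functions ships in
`inst/cli/gmsca.R` (subcommands `simulate`, `network`, `enrich`, `run`).

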