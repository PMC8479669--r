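#' Simulate bulk expression with planted cell-type modules
#'
#' Generates a genes x samples matrix under an additive latent-factor model
#' of bulk tissue: each sample has one independent standard-normal latent
#' signal per cell type (\eqn{x_c}) plus a shared background factor
#' (\eqn{x_0}). A gene in the module of cell type c is
#' \eqn{e_g = \alpha_g x_c + \beta_g x_0 + \varepsilon}; a multifunctional
#' gene with type pair (A, B) additionally loads on B's latent with a
#' weaker coefficient, \eqn{e_g = \alpha_g x_A + \alpha'_g x_B + \beta_g x_0
#' + \varepsilon}; background genes carry only \eqn{\beta_g x_0 +
#' \varepsilon}. Loadings are folded normals centered on the `loading_*`
#' arguments (sd 0.1) and \eqn{\varepsilon \sim N(0, noise\_sd^2)}.
#' Multifunctional pairs are the disjoint consecutive cell-type pairs
#' (1st with 2nd, 3rd with 4th, ...), and each multifunctional gene belongs
#' to its primary (first) type's module. Fully deterministic given `seed`.
#'
#' With the defaults (4 cell types x 300 module genes of which 60 are
#' markers, 40 multifunctional genes per disjoint pair, 800 background
#' genes, 150 samples) the matrix is 2080 genes x 150 samples.
#'
#' @param n_samples Samples (>= 10; default 150).
#' @param cell_types Named integer vector cell type -> module size
#'   (multifunctional genes come on top of these counts).
#' @param n_markers Designated marker genes per cell type (default 60).
#' @param n_multifunctional Genes per disjoint adjacent type pair
#'   (default 40).
#' @param n_background_genes Background-only genes (default 800).
#' @param loading_primary Mean loading on the dominant type (default 1.0).
#' @param loading_secondary Mean loading of multifunctional genes on their
#'   second type (default 0.6).
#' @param loading_background Mean loading on the shared factor
#'   (default 0.5).
#' @param noise_sd Noise standard deviation (default 1).
#' @param seed Integer seed (mandatory).
#' @return List of class `synthetic_dataset`: `expr` (matrix),
#'   `truth_modules` (gene -> cell type or "background"), `truth_markers`
#'   (list type -> genes), `truth_multifunctional` (data.frame `gene`,
#'   `primary`, `secondary`), `latent_factors` (samples x factors matrix),
#'   `config`.
#' @export
simulate_bulk <- function(n_samples = 150,
                          cell_types = c(neuron = 300, astrocyte = 300,
                                         microglia = 300, oligodendrocyte = 300),
                          n_markers = 60, n_multifunctional = 40,
                          n_background_genes = 800,
                          loading_primary = 1.0, loading_secondary = 0.6,
                          loading_background = 0.5, noise_sd = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_samples < 10) stop("need at least 10 samples for stable networks")
  if (is.null(names(cell_types)) || any(!nzchar(names(cell_types))))
    stop("cell_types must be a named vector of module sizes")
  if (any(cell_types < n_markers))
    stop("each module must be at least as large as its marker count")
  types <- names(cell_types)
  pairs <- if (length(types) >= 2 && n_multifunctional > 0) {
    lapply(seq(1, 2 * (length(types) %/% 2), by = 2),
           function(i) types[c(i, i + 1)])
  } else list()

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  latent <- matrix(stats::rnorm(n_samples * (length(types) + 1)), n_samples,
                   dimnames = list(samples, c(types, "x0")))

  fold <- function(n, mu) abs(stats::rnorm(n, mu, 0.1))
  rows <- list(); truth <- character(0); markers <- stats::setNames(
    vector("list", length(types)), types)
  mf_rows <- list()

  for (ct in types) {
    n_mod <- cell_types[[ct]]
    a <- fold(n_mod, loading_primary)
    b <- fold(n_mod, loading_background)
    block <- outer(a, latent[, ct]) + outer(b, latent[, "x0"]) +
      matrix(stats::rnorm(n_mod * n_samples, 0, noise_sd), n_mod)
    rows[[ct]] <- block
    truth <- c(truth, rep(ct, n_mod))
  }
  for (pr in pairs) {
    a <- fold(n_multifunctional, loading_primary)
    a2 <- fold(n_multifunctional, loading_secondary)
    b <- fold(n_multifunctional, loading_background)
    block <- outer(a, latent[, pr[1]]) + outer(a2, latent[, pr[2]]) +
      outer(b, latent[, "x0"]) +
      matrix(stats::rnorm(n_multifunctional * n_samples, 0, noise_sd),
             n_multifunctional)
    rows[[paste(pr, collapse = "_")]] <- block
    truth <- c(truth, rep(pr[1], n_multifunctional))
    mf_rows[[paste(pr, collapse = "_")]] <-
      data.frame(primary = pr[1], secondary = pr[2],
                 idx = length(truth) - n_multifunctional + seq_len(n_multifunctional))
  }
  if (n_background_genes > 0) {
    b <- fold(n_background_genes, loading_background)
    rows[["background"]] <- outer(b, latent[, "x0"]) +
      matrix(stats::rnorm(n_background_genes * n_samples, 0, noise_sd),
             n_background_genes)
    truth <- c(truth, rep("background", n_background_genes))
  }
  expr <- do.call(rbind, rows)
  genes <- sprintf("G%04d", seq_len(nrow(expr)))
  dimnames(expr) <- list(genes, samples)
  names(truth) <- genes
  offset <- 0L
  for (ct in types) {
    markers[[ct]] <- genes[offset + seq_len(n_markers)]
    offset <- offset + cell_types[[ct]]
  }
  truth_mf <- if (length(mf_rows) > 0) {
    mf <- do.call(rbind, mf_rows)
    data.frame(gene = genes[mf$idx], primary = mf$primary,
               secondary = mf$secondary, stringsAsFactors = FALSE)
  } else data.frame(gene = character(0), primary = character(0),
                    secondary = character(0), stringsAsFactors = FALSE)
  rownames(truth_mf) <- NULL
  structure(list(
    expr = expr, truth_modules = truth, truth_markers = markers,
    truth_multifunctional = truth_mf, latent_factors = latent,
    config = list(n_samples = n_samples, cell_types = cell_types,
                  n_markers = n_markers, n_multifunctional = n_multifunctional,
                  n_background_genes = n_background_genes,
                  loading_primary = loading_primary,
                  loading_secondary = loading_secondary,
                  loading_background = loading_background,
                  noise_sd = noise_sd, seed = seed)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  cat("  cell types:", paste(names(x$config$cell_types), collapse = ", "), "\n")
  cat("  multifunctional genes:", nrow(x$truth_multifunctional),
      " background genes:", x$config$n_background_genes, "\n")
  invisible(x)
}

# Pair-counting adjusted Rand index via mclust.
adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

#' Score a network (and optionally a gene-state table) against the truth
#'
#' @param network `coexpression_network` built on a simulated matrix.
#' @param truth `synthetic_dataset` from \code{\link{simulate_bulk}}.
#' @param mapping Optional module -> cell type mapping from
#'   \code{\link{assign_cell_types}}; enables the marker hit-rate metric.
#' @param states Optional `states` data.frame from
#'   \code{\link{aggregate_states}}; enables the multifunctionality
#'   metrics.
#' @return Named list of metrics: `ari_all` (background genes included),
#'   `ari_modules` (planted module genes only); with `mapping`:
#'   `celltype_hit_rate` (fraction of planted types recovered by exactly
#'   one enriched module) and `n_enriched_modules`; with `states`:
#'   `multifunctional_sensitivity` (planted dual-loading genes classified
#'   multifunctional toward their planted secondary type) and
#'   `false_multifunctional_rate` (pure single-type genes flagged
#'   multifunctional).
#' @export
evaluate_recovery <- function(network, truth, mapping = NULL, states = NULL) {
  genes <- names(network$assignment)
  tm <- truth$truth_modules[genes]
  if (anyNA(tm)) stop("network genes missing from the truth table")
  out <- list(ari_all = adjusted_rand(network$assignment, tm))
  in_mod <- tm != "background"
  out$ari_modules <- adjusted_rand(network$assignment[in_mod], tm[in_mod])
  if (!is.null(mapping)) {
    types <- names(truth$truth_markers)
    hits <- vapply(types, function(ct) sum(mapping == ct) == 1, logical(1))
    out$celltype_hit_rate <- mean(hits)
    out$n_enriched_modules <- length(mapping)
  }
  if (!is.null(states)) {
    mf <- truth$truth_multifunctional
    if (nrow(mf) > 0) {
      st <- states[match(mf$gene, states$gene), ]
      got <- st$multifunctional_any &
        mapply(function(cts, sec) sec %in% strsplit(cts, ";")[[1]],
               st$cell_types, mf$secondary)
      out$multifunctional_sensitivity <- mean(got)
    }
    pure <- setdiff(genes[in_mod], mf$gene)
    stp <- states[match(pure, states$gene), ]
    out$false_multifunctional_rate <- mean(stp$multifunctional_any)
  }
  out
}

#' Write a simulated dataset to a directory
#'
#' Writes `expr.tsv` (genes x samples), `truth_modules.tsv`,
#' `truth_multifunctional.tsv` and `markers.gmt`.
#'
#' @param sim `synthetic_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(sim$expr), sim$expr, check.names = FALSE),
    file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(sim$truth_modules),
               module = unname(sim$truth_modules)),
    file.path(dir, "truth_modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$truth_multifunctional,
                     file.path(dir, "truth_multifunctional.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$truth_markers, file.path(dir, "markers.gmt"))
  invisible(dir)
}
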