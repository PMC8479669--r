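#' One-sided Fisher enrichment of a module against a marker set
#'
#' Intersects the marker set with the background, builds the 2x2 table
#' (overlap; module without markers; markers without module; rest) and
#' returns the one-sided (enrichment) Fisher exact p-value, i.e. the upper
#' hypergeometric tail at the observed overlap.
#'
#' @param module_genes Character vector, subset of `background`.
#' @param markers Character vector of marker gene ids (intersected with the
#'   background before testing).
#' @param background Character vector: the full gene universe.
#' @return List with `overlap`, `module_size`, `marker_size` (within
#'   background) and `p_raw`.
#' @export
marker_fisher <- function(module_genes, markers, background) {
  if (length(background) == 0) stop("empty background gene set")
  background <- unique(background)
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% background))
    stop("module genes must be a subset of the background")
  markers <- intersect(unique(markers), background)
  ov <- length(intersect(module_genes, markers))
  list(overlap = ov,
       module_size = length(module_genes),
       marker_size = length(markers),
       p_raw = hyper_tail_p(ov, length(module_genes), length(markers),
                            length(background)))
}

# P(X >= ov) for X ~ Hypergeometric(N, K markers, n module draws);
# exact one-sided Fisher enrichment p-value. Vectorized over all arguments.
hyper_tail_p <- function(ov, n_module, n_marker, n_background) {
  ifelse(ov == 0, 1,
         stats::phyper(ov - 1, n_marker, n_background - n_marker, n_module,
                       lower.tail = FALSE))
}

#' Regress the module-size effect out of enrichment significance
#'
#' Module size correlates with -log10 enrichment p-values, inflating
#' positives in large modules. This fits OLS of -log10(p_bonferroni) on
#' module size across all rows and keeps the residual; a test is `enriched`
#' only when its Bonferroni p-value is below `alpha` *and* its residual is
#' positive (more significant than its size predicts).
#'
#' @param table data.frame with columns `module`, `cell_type`,
#'   `module_size`, `overlap`, `p_raw`, `p_bonferroni`.
#' @param alpha Significance level for the Bonferroni bound (default 0.05).
#' @return The table with `neglog10_adjusted` and `enriched` columns added.
#' @export
size_adjust <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table),
            all(c("module_size", "p_bonferroni") %in% names(table)))
  y <- -log10(pmax(table$p_bonferroni, 1e-300))
  if (nrow(table) < 3) {
    warning("fewer than 3 tests; module-size adjustment skipped")
    table$neglog10_adjusted <- y
  } else if (length(unique(table$module_size)) < 2) {
    # no size variation: slope drops, intercept-only fit centers the values
    table$neglog10_adjusted <- y - mean(y)
  } else {
    fit <- stats::lm(y ~ table$module_size)
    table$neglog10_adjusted <- unname(stats::residuals(fit))
  }
  # residual must be positive beyond round-off, so exact size artifacts
  # (residual ~ 1e-16) do not count as enrichment
  table$enriched <- table$p_bonferroni < alpha & table$neglog10_adjusted > 1e-10
  table
}

#' Annotate network modules with cell types
#'
#' Runs \code{\link{marker_fisher}} for every (module, cell type) pair with
#' the network's full gene pool as background, applies Bonferroni correction
#' over all tests in the table, the module-size adjustment of
#' \code{\link{size_adjust}}, and finally the single-cell-type rule: when a
#' module passes for several cell types only the most significant one keeps
#' `enriched = TRUE` (ties broken by larger adjusted residual, then
#' alphabetical cell-type name), since a second, marginal signal is dropped.
#'
#' @param network `coexpression_network`.
#' @param marker_collection Named list of character vectors: cell type ->
#'   marker gene ids (e.g. from \code{\link{read_gmt}}).
#' @param alpha Bonferroni significance level (default 0.05).
#' @return List with `table` (the full enrichment data.frame) and `mapping`
#'   (named character vector module -> cell type, enriched modules only).
#' @export
assign_cell_types <- function(network, marker_collection, alpha = 0.05) {
  stopifnot(inherits(network, "coexpression_network"))
  if (is.null(names(marker_collection)))
    stop("marker_collection must be a named list (cell type -> genes)")
  background <- names(network$assignment)
  modules <- setdiff(sort(unique(network$assignment)), UNASSIGNED)
  usable <- character(0)
  for (ct in names(marker_collection)) {
    if (length(intersect(marker_collection[[ct]], background)) == 0) {
      warning("marker set '", ct, "' has no genes in the background; skipped")
    } else usable <- c(usable, ct)
  }
  if (length(modules) == 0 || length(usable) == 0) {
    return(list(table = empty_enrichment_table(), mapping = character(0)))
  }
  rows <- list()
  for (m in modules) {
    mg <- background[network$assignment == m]
    for (ct in usable) {
      ft <- marker_fisher(mg, marker_collection[[ct]], background)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, cell_type = ct, module_size = ft$module_size,
        overlap = ft$overlap, p_raw = ft$p_raw,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_bonferroni <- pmin(1, tab$p_raw * nrow(tab))
  tab <- size_adjust(tab, alpha = alpha)
  # single-cell-type rule
  for (m in unique(tab$module[tab$enriched])) {
    idx <- which(tab$module == m & tab$enriched)
    if (length(idx) > 1) {
      o <- order(tab$p_bonferroni[idx], -tab$neglog10_adjusted[idx],
                 tab$cell_type[idx])
      drop <- idx[o[-1]]
      message("module ", m, ": dropping marginal cell-type signal(s) ",
              paste(tab$cell_type[drop], collapse = ", "))
      tab$enriched[drop] <- FALSE
    }
  }
  mapping <- stats::setNames(tab$cell_type[tab$enriched], tab$module[tab$enriched])
  list(table = tab, mapping = mapping)
}

empty_enrichment_table <- function() {
  data.frame(module = character(0), cell_type = character(0),
             module_size = integer(0), overlap = integer(0),
             p_raw = numeric(0), p_bonferroni = numeric(0),
             neglog10_adjusted = numeric(0), enriched = logical(0),
             stringsAsFactors = FALSE)
}

#' Generic gene-set over-representation for module function annotation
#'
#' Applies the same Fisher machinery to arbitrary annotation sets (GO terms,
#' pathways, ...) supplied as a GMT collection, with Bonferroni correction
#' over all (module, term) tests. Used to attach function terms to modules
#' for triplet generation.
#'
#' @param network `coexpression_network`.
#' @param term_sets Named list term -> gene ids.
#' @param alpha Bonferroni level (default 0.05).
#' @return Named list module -> character vector of significant term names
#'   (possibly empty).
#' @export
annotate_module_functions <- function(network, term_sets, alpha = 0.05) {
  stopifnot(inherits(network, "coexpression_network"))
  background <- names(network$assignment)
  modules <- setdiff(sort(unique(network$assignment)), UNASSIGNED)
  out <- stats::setNames(vector("list", length(modules)), modules)
  if (length(modules) == 0 || length(term_sets) == 0) return(out)
  praw <- list(); key <- list()
  for (m in modules) {
    mg <- background[network$assignment == m]
    for (term in names(term_sets)) {
      if (length(intersect(term_sets[[term]], background)) == 0) next
      ft <- marker_fisher(mg, term_sets[[term]], background)
      praw[[length(praw) + 1L]] <- ft$p_raw
      key[[length(key) + 1L]] <- c(m, term)
    }
  }
  if (length(praw) == 0) {
    for (m in modules) out[[m]] <- character(0)
    return(out)
  }
  p <- pmin(1, unlist(praw) * length(praw))
  for (m in modules) out[[m]] <- character(0)
  for (i in seq_along(p)) {
    if (p[i] < alpha) out[[key[[i]][1]]] <- c(out[[key[[i]][1]]], key[[i]][2])
  }
  out
}
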