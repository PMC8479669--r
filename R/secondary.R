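#' Remove a cell type's principal-component signal from a module
#'
#' Under the additive model of gene expression in bulk tissue — each gene's
#' expression is a weighted sum of per-sample cell-type contributions plus a
#' shared background factor and noise — the dominant principal component of
#' a cell-type-enriched module is taken to be that cell type's contribution.
#' Each gene row is centered, the singular value decomposition of the
#' centered submatrix is taken, `k` is the smallest number of components
#' whose cumulative explained variance reaches \code{variance_target}, and
#' the submatrix is reconstructed from components 2..k only (dropping both
#' the first component and the tail beyond the variance target); gene means
#' are then added back.
#'
#' @param submatrix genes x samples matrix restricted to one module
#'   (>= 2 genes, >= 3 samples).
#' @param variance_target Cumulative explained-variance rule defining `k`
#'   (default 0.90).
#' @param tail `"drop"` (default) reconstructs from components 2..k;
#'   `"keep"` uses all components but the first.
#' @return List with `corrected` (same shape and dimnames) and `report`
#'   (data.frame: `genes`, `n_components_90`, `variance_removed` = PC1
#'   variance share).
#' @export
remove_cell_signal <- function(submatrix, variance_target = 0.90,
                               tail = c("drop", "keep")) {
  tail <- match.arg(tail)
  if (nrow(submatrix) < 2) stop("need at least 2 genes in the module")
  if (ncol(submatrix) < 3) stop("need at least 3 samples")
  mu <- rowMeans(submatrix)
  X <- submatrix - mu
  sv <- svd(X)
  var_share <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(var_share) >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(sv$d)
  if (k == 1 && tail == "drop") {
    warning("first component alone reaches the variance target; ",
            "corrected module collapses to its gene means (inert in the secondary network)")
    corrected <- matrix(mu, nrow = nrow(submatrix), ncol = ncol(submatrix),
                        dimnames = dimnames(submatrix))
  } else {
    hi <- if (tail == "drop") k else length(sv$d)
    keep <- if (hi >= 2) seq(2, hi) else integer(0)
    keep <- keep[sv$d[keep] > 0]
    if (length(keep) == 0) {
      corrected <- matrix(mu, nrow = nrow(submatrix), ncol = ncol(submatrix),
                          dimnames = dimnames(submatrix))
    } else {
      recon <- sv$u[, keep, drop = FALSE] %*%
        (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
      corrected <- recon + mu
      dimnames(corrected) <- dimnames(submatrix)
    }
  }
  list(corrected = corrected,
       report = data.frame(genes = nrow(submatrix),
                           n_components_90 = as.integer(k),
                           variance_removed = var_share[1]))
}

#' Build the cell-type-corrected expression matrix
#'
#' Copies the full expression matrix and replaces the rows of every module
#' mapped to \code{cell_type} with their \code{\link{remove_cell_signal}}
#' output; all other genes are untouched. The per-module removal reports are
#' attached as the `"removal_reports"` attribute.
#'
#' @param expr Full genes x samples matrix.
#' @param network `coexpression_network` built from `expr`.
#' @param module_celltypes Named vector module -> cell type (from
#'   \code{\link{assign_cell_types}}).
#' @param cell_type Cell type whose signal to remove.
#' @param variance_target,tail Passed to \code{\link{remove_cell_signal}}.
#' @return Corrected matrix, same shape and dimnames as `expr`.
#' @export
build_secondary_matrix <- function(expr, network, module_celltypes, cell_type,
                                   variance_target = 0.90,
                                   tail = c("drop", "keep")) {
  tail <- match.arg(tail)
  if (!cell_type %in% module_celltypes)
    stop("cell type '", cell_type, "' has no enriched module; available: ",
         paste(unique(module_celltypes), collapse = ", "))
  mods <- names(module_celltypes)[module_celltypes == cell_type]
  out <- expr
  reports <- list()
  for (m in mods) {
    genes <- names(network$assignment)[network$assignment == m]
    genes <- intersect(genes, rownames(expr))
    rem <- remove_cell_signal(expr[genes, , drop = FALSE],
                              variance_target = variance_target, tail = tail)
    out[genes, ] <- rem$corrected
    rep <- rem$report
    rep$module <- m
    rep$cell_type <- cell_type
    reports[[m]] <- rep
  }
  attr(out, "removal_reports") <- do.call(rbind, reports)
  out
}

#' Build one secondary network per enriched cell type
#'
#' For every cell type with at least one enriched module in the primary
#' network, removes that cell type's signal
#' (\code{\link{build_secondary_matrix}}) and rebuilds a co-expression
#' network on the full corrected gene pool, with provenance
#' `"secondary:<cell type>"`. The soft power is re-selected per corrected
#' matrix by default, since signal removal changes the correlation
#' structure materially.
#'
#' @param expr Full genes x samples matrix.
#' @param network Primary `coexpression_network`.
#' @param module_celltypes Named vector module -> cell type.
#' @param variance_target,tail Signal-removal parameters.
#' @param reuse_power If `TRUE`, reuse the primary network's soft power
#'   instead of re-selecting (default `FALSE`).
#' @param power Fixed soft power for the secondary networks; `NULL`
#'   (default) re-selects per corrected matrix (ignored when
#'   `reuse_power` is set).
#' @param ... Further arguments passed to \code{\link{build_network}}.
#' @return Named list cell type -> `coexpression_network`; each element
#'   carries the `"removal_reports"` attribute of its corrected matrix.
#' @export
build_all_secondary <- function(expr, network, module_celltypes,
                                variance_target = 0.90, tail = "drop",
                                reuse_power = FALSE, power = NULL, ...) {
  cts <- unique(unname(module_celltypes))
  if (length(cts) == 0) {
    warning("no enriched cell types; no secondary networks built")
    return(stats::setNames(list(), character(0)))
  }
  out <- list()
  for (ct in cts) {
    corrected <- build_secondary_matrix(expr, network, module_celltypes, ct,
                                        variance_target = variance_target,
                                        tail = tail)
    sgcn <- build_network(corrected,
                          power = if (reuse_power) network$soft_power else power,
                          provenance = paste0("secondary:", ct), ...)
    attr(sgcn, "removal_reports") <- attr(corrected, "removal_reports")
    out[[ct]] <- sgcn
  }
  out
}
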