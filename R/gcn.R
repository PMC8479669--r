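UNASSIGNED <- "unassigned"

# adjacency a_ij = |cor|^power (unsigned) or max(cor,0)^power (signed_hybrid),
# diagonal forced to 0 so connectivity k_i = sum_{u != i} a_iu is a row sum.
adjacency_matrix <- function(expr, power, network_type = c("unsigned", "signed_hybrid")) {
  network_type <- match.arg(network_type)
  if (power < 1) stop("power must be >= 1")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene row(s) (e.g. ",
         rownames(expr)[which(sds == 0)[1]],
         "); run drop_constant_genes()/residualize() first")
  C <- stats::cor(t(expr))
  A <- if (network_type == "unsigned") abs(C)^power else pmax(C, 0)^power
  diag(A) <- 0
  A
}

#' Choose the soft-thresholding power for scale-free topology
#'
#' For each candidate power the weighted connectivity \eqn{k_i = \sum_{j \ne i}
#' |cor(i,j)|^\beta} is computed, binned into \code{n_bins} equal-width bins,
#' and the scale-free fit is the R-squared of the regression of log10 bin
#' frequency on log10 mean bin connectivity, sign-corrected (negated when the
#' slope is positive, since scale-free topology requires a decreasing law).
#' The smallest power reaching \code{fit_threshold} is returned; if none does,
#' the power with maximal fit is returned with a warning.
#'
#' @param expr genes x samples numeric matrix (>= 10 genes).
#' @param powers Integer candidate grid (default 1:30).
#' @param fit_threshold Required signed R-squared (default 0.80).
#' @param network_type `"unsigned"` or `"signed_hybrid"`.
#' @param n_bins Connectivity histogram bins (default 10).
#' @return Integer power; attribute `"fit"` carries the per-power signed
#'   R-squared values.
#' @export
select_soft_power <- function(expr, powers = 1:30, fit_threshold = 0.80,
                              network_type = c("unsigned", "signed_hybrid"),
                              n_bins = 10) {
  network_type <- match.arg(network_type)
  if (length(powers) == 0) stop("powers grid is empty")
  if (nrow(expr) < 10) stop("need at least 10 genes to assess scale-free fit")
  C <- stats::cor(t(expr))
  if (anyNA(C)) stop("constant gene row(s); run drop_constant_genes() first")
  S <- if (network_type == "unsigned") abs(C) else pmax(C, 0)
  diag(S) <- 0
  fits <- vapply(powers, function(p) {
    k <- rowSums(S^p)
    scale_free_fit(k, n_bins = n_bins)
  }, numeric(1))
  names(fits) <- as.character(powers)
  ok <- which(fits >= fit_threshold)
  if (length(ok) > 0) {
    chosen <- powers[min(ok)]
  } else {
    chosen <- powers[which.max(fits)]
    warning(sprintf(
      "no power in the grid reaches scale-free fit %.2f (best %.2f at power %d); using it",
      fit_threshold, max(fits), chosen))
  }
  structure(as.integer(chosen), fit = fits)
}

# Signed scale-free model fit from a connectivity vector: bin k, regress
# log10(frequency) on log10(mean k) over occupied bins.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  kmean <- vapply(split(k, bin), function(x) if (length(x)) mean(x) else NA_real_,
                  numeric(1))
  keep <- freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(keep) < 3) return(NA_real_)
  x <- log10(kmean[keep]); y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[["x"]]
  -sign(slope) * r2
}

#' Topological overlap matrix
#'
#' Computes the standard unsigned topological overlap
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}, where the adjacency is
#' \eqn{a_{ij} = |cor(i,j)|^{power}} (unsigned) or
#' \eqn{\max(cor, 0)^{power}} (signed hybrid). Diagonal entries are 1.
#'
#' @param expr genes x samples numeric matrix; no constant rows.
#' @param power Soft-thresholding power (>= 1).
#' @param network_type `"unsigned"` (default) or `"signed_hybrid"`.
#' @return Symmetric genes x genes matrix with entries in [0, 1].
#' @export
tom_matrix <- function(expr, power, network_type = c("unsigned", "signed_hybrid")) {
  network_type <- match.arg(network_type)
  A <- adjacency_matrix(expr, power, network_type)
  k <- rowSums(A)
  L <- A %*% A                       # diag(A)=0, so L_ij = l_ij for i != j
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2          # kill round-off asymmetry
  dimnames(tom) <- list(rownames(expr), rownames(expr))
  tom
}

#' Initial module detection by hierarchical clustering of 1 - TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM.
#' The dendrogram is cut at the merge height that yields the largest number
#' of clusters with at least \code{min_module_size} genes (ties broken toward
#' the lower height: tied low cuts may leave cluster tails unassigned, which
#' the k-means refinement reattaches, whereas tied high cuts can merge
#' distinct modules, which no later stage can undo); clusters below the size
#' floor are relabeled
#' `"unassigned"`. Retained modules are labeled `"M1"`, `"M2"`, ... in
#' decreasing size order.
#'
#' @param tom Symmetric TOM matrix with gene dimnames.
#' @param min_module_size Minimum genes per module (default 100).
#' @return Named character vector gene id -> module label.
#' @export
initial_modules <- function(tom, min_module_size = 100) {
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  genes <- rownames(tom)
  if (is.null(genes)) stop("TOM needs gene dimnames")
  if (min_module_size > length(genes)) {
    warning("min_module_size exceeds gene count; all genes unassigned")
    return(stats::setNames(rep(UNASSIGNED, length(genes)), genes))
  }
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  heights <- sort(unique(tree$height))
  cuts <- stats::cutree(tree, h = heights)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
  n_big <- apply(cuts, 2, function(cl) sum(table(cl) >= min_module_size))
  best <- which.max(n_big)   # ties -> lowest height; refinement reattaches tails
  cl <- cuts[, best]
  relabel_by_size(cl, genes, min_module_size)
}

# integer cluster vector -> "M1".."Mk" by decreasing size, small ones unassigned
relabel_by_size <- function(cl, genes, min_module_size) {
  tab <- sort(table(cl), decreasing = TRUE)
  big <- names(tab)[tab >= min_module_size]
  lab <- rep(UNASSIGNED, length(cl))
  for (i in seq_along(big)) lab[cl == big[i]] <- paste0("M", i)
  stats::setNames(lab, genes)
}

#' Module eigengene: first principal component of a module
#'
#' Rows of the module submatrix are standardized (zero mean, unit variance),
#' the first right singular vector of the standardized submatrix gives the
#' per-sample scores, which are scaled to unit variance and sign-flipped so
#' that the mean correlation with the member genes is non-negative.
#'
#' @param expr genes x samples numeric matrix.
#' @param member_genes Character vector of >= 2 gene ids present in `expr`.
#' @return Numeric sample vector (named by sample id) with unit variance.
#' @export
module_eigengene <- function(expr, member_genes) {
  missing <- setdiff(member_genes, rownames(expr))
  if (length(missing) > 0)
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (length(member_genes) < 2) stop("need at least 2 member genes")
  X <- expr[member_genes, , drop = FALSE]
  Xs <- t(scale(t(X)))               # per-gene z-score
  if (anyNA(Xs)) stop("constant gene row inside module; run drop_constant_genes() first")
  sv <- svd(Xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  e <- e / stats::sd(e)
  if (mean(stats::cor(t(Xs), e)) < 0) e <- -e
  stats::setNames(e, colnames(expr))
}

# eigengene matrix (samples x modules) for every non-unassigned module
compute_eigengenes <- function(expr, assignment) {
  mods <- setdiff(sort(unique(assignment)), UNASSIGNED)
  if (length(mods) == 0) return(NULL)
  E <- vapply(mods, function(m)
    module_eigengene(expr, names(assignment)[assignment == m]),
    numeric(ncol(expr)))
  rownames(E) <- colnames(expr)
  E
}

#' k-means-style refinement of a module assignment
#'
#' Iterates (at most \code{max_iter} times, default 50): compute each module's
#' eigengene; reassign every gene (including unassigned ones) to the module
#' whose eigengene it correlates with most strongly in absolute value,
#' provided that correlation reaches \code{reassign_floor}, otherwise
#' `"unassigned"`; stop early when no gene moves. Modules falling below
#' \code{min_module_size} at the end are dissolved into `"unassigned"`.
#'
#' @param expr genes x samples matrix.
#' @param assignment Named gene -> module vector with >= 1 real module.
#' @param max_iter Maximum refinement iterations (default 50).
#' @param reassign_floor Minimum absolute eigengene correlation to keep a
#'   gene in a module (default 0.3).
#' @param min_module_size Size floor applied after convergence (default 100).
#' @return Refined named assignment vector.
#' @export
kmeans_refine <- function(expr, assignment, max_iter = 50,
                          reassign_floor = 0.3, min_module_size = 100) {
  if (!any(assignment != UNASSIGNED)) stop("assignment has no module to refine")
  assignment <- assignment[rownames(expr)]
  if (max_iter < 1) return(assignment)
  for (iter in seq_len(max_iter)) {
    E <- compute_eigengenes(expr, assignment)
    if (is.null(E)) break
    MM <- stats::cor(t(expr), E)     # genes x modules
    best <- max.col(abs(MM), ties.method = "first")
    bestval <- abs(MM)[cbind(seq_len(nrow(MM)), best)]
    new_assign <- ifelse(bestval >= reassign_floor, colnames(E)[best], UNASSIGNED)
    names(new_assign) <- rownames(expr)
    if (identical(unname(new_assign), unname(assignment))) break
    assignment <- new_assign
  }
  tab <- table(assignment[assignment != UNASSIGNED])
  small <- names(tab)[tab < min_module_size]
  assignment[assignment %in% small] <- UNASSIGNED
  assignment
}

#' Module membership (MM): gene-eigengene correlations
#'
#' @param expr genes x samples matrix.
#' @param eigengenes samples x modules eigengene matrix.
#' @return genes x modules matrix of Pearson correlations in [-1, 1].
#' @export
module_membership <- function(expr, eigengenes) {
  if (is.null(eigengenes)) stop("network has no eigengenes")
  MM <- stats::cor(t(expr), eigengenes)
  dimnames(MM) <- list(rownames(expr), colnames(eigengenes))
  MM
}

#' Build a co-expression network
#'
#' Full construction pipeline: soft-power selection (unless `power` is
#' given), adjacency and TOM, average-linkage clustering of 1 - TOM with a
#' minimum module size, k-means-style refinement against module eigengenes,
#' final eigengenes and module membership. Deterministic for a given input.
#'
#' @param expr genes x samples matrix (constant rows are dropped with a
#'   warning).
#' @param power Soft power; `NULL` (default) selects it from the data.
#' @param powers Candidate grid when selecting (default 1:30).
#' @param fit_threshold Scale-free fit target (default 0.80).
#' @param network_type `"unsigned"` or `"signed_hybrid"`.
#' @param min_module_size Minimum module size (default 100).
#' @param max_kmeans_iter Refinement iterations (default 50).
#' @param reassign_floor Refinement correlation floor (default 0.3).
#' @param provenance `"primary"` (default) or `"secondary:<cell type>"`.
#' @return Object of class `coexpression_network`: list with `soft_power`,
#'   `assignment` (gene -> module), `eigengenes` (samples x modules),
#'   `membership` (genes x modules), `provenance`, `params`.
#' @export
build_network <- function(expr, power = NULL, powers = 1:30,
                          fit_threshold = 0.80,
                          network_type = c("unsigned", "signed_hybrid"),
                          min_module_size = 100, max_kmeans_iter = 50,
                          reassign_floor = 0.3, provenance = "primary") {
  network_type <- match.arg(network_type)
  validate_expression(expr)
  expr <- drop_constant_genes(expr)
  if (is.null(power)) {
    power <- select_soft_power(expr, powers = powers,
                               fit_threshold = fit_threshold,
                               network_type = network_type)
  }
  tom <- tom_matrix(expr, power, network_type)
  assignment <- initial_modules(tom, min_module_size)
  if (any(assignment != UNASSIGNED)) {
    assignment <- kmeans_refine(expr, assignment, max_iter = max_kmeans_iter,
                                reassign_floor = reassign_floor,
                                min_module_size = min_module_size)
  }
  eigengenes <- compute_eigengenes(expr, assignment)
  membership <- if (!is.null(eigengenes)) module_membership(expr, eigengenes) else NULL
  structure(list(
    soft_power = as.integer(power),
    assignment = assignment,
    eigengenes = eigengenes,
    membership = membership,
    provenance = provenance,
    params = list(network_type = network_type,
                  min_module_size = min_module_size,
                  max_kmeans_iter = max_kmeans_iter,
                  reassign_floor = reassign_floor,
                  fit_threshold = fit_threshold)
  ), class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  mods <- setdiff(unique(x$assignment), UNASSIGNED)
  cat("coexpression_network (", x$provenance, ")\n", sep = "")
  cat("  genes:", length(x$assignment),
      " modules:", length(mods),
      " unassigned:", sum(x$assignment == UNASSIGNED), "\n")
  cat("  soft power:", x$soft_power, "\n")
  invisible(x)
}

#' Write a network to a directory of delimited files
#'
#' Writes `assignment.tsv` (gene, module), `eigengenes.tsv`
#' (sample x module), `membership.tsv` (gene x module) and a `network.json`
#' sidecar with soft power, parameters and provenance.
#'
#' @param network `coexpression_network` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(gene_id = names(network$assignment),
               module = unname(network$assignment)),
    file.path(dir, "assignment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(network$eigengenes)) {
    utils::write.table(
      data.frame(sample_id = rownames(network$eigengenes),
                 network$eigengenes, check.names = FALSE),
      file.path(dir, "eigengenes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = rownames(network$membership),
                 network$membership, check.names = FALSE),
      file.path(dir, "membership.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(soft_power = network$soft_power,
         provenance = network$provenance,
         params = network$params),
    file.path(dir, "network.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
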