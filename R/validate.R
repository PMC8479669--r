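#' Permutation Z-summary for module preservation
#'
#' Tests whether a module defined in a reference dataset keeps its
#' co-expression structure in a test dataset, with two statistics:
#' *density* (mean absolute pairwise correlation among the module genes in
#' the test data) and *connectivity* (Spearman correlation between the
#' genes' intramodular connectivity — row sums of absolute correlation — in
#' reference vs test). Each statistic is compared with its permutation null
#' over random same-size gene sets drawn from the test data, giving
#' z-scores; `z_summary` is their mean. Z above 10 indicates strong
#' preservation, above 2 weak preservation, below 2 none.
#'
#' This is a deliberate two-statistic simplification of the full WGCNA
#' modulePreservation battery that keeps the published thresholds'
#' semantics; values are not numerically identical to WGCNA's.
#'
#' @param ref_expr,test_expr genes x samples matrices sharing the module
#'   genes (connectivity is computed within the module in both).
#' @param ref_module Character vector of >= 3 module gene ids.
#' @param n_perm Number of permutations (default 200, minimum 100).
#' @param seed Integer seed for the permutation draws.
#' @return data.frame with `z_summary`, `z_density`, `z_connectivity`,
#'   `density_observed`, `connectivity_observed`, `n_permutations`.
#' @export
preservation_z <- function(ref_expr, ref_module, test_expr, n_perm = 200,
                           seed = 1) {
  if (length(ref_module) < 3) stop("module must have at least 3 genes")
  if (n_perm < 100) stop("n_perm must be >= 100")
  missing <- setdiff(ref_module, intersect(rownames(ref_expr), rownames(test_expr)))
  if (length(missing) > 0)
    stop("module gene(s) absent from one matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  m <- length(ref_module)
  stat_pair <- function(genes) {
    Ct <- stats::cor(t(test_expr[genes, , drop = FALSE]))
    Cr <- stats::cor(t(ref_expr[genes, , drop = FALSE]))
    density <- mean(abs(Ct[upper.tri(Ct)]))
    k_ref <- rowSums(abs(Cr)) - 1
    k_test <- rowSums(abs(Ct)) - 1
    connectivity <- stats::cor(rank(k_ref), rank(k_test))
    c(density, connectivity)
  }
  obs <- stat_pair(ref_module)
  pool <- sort(rownames(test_expr))   # order-invariant permutation draws
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) stat_pair(sample(pool, m)),
                 numeric(2))
  z <- (obs - rowMeans(null)) / apply(null, 1, stats::sd)
  data.frame(z_summary = mean(z), z_density = z[1], z_connectivity = z[2],
             density_observed = obs[1], connectivity_observed = obs[2],
             n_permutations = n_perm)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Boolean cell-type specificity from sorted-cell expression profiles
#'
#' For immunopanning-style reference profiles: replicate columns of the same
#' cell type (duplicate column names) are averaged, the matrix is
#' log2(x + 1)-transformed and standardized as a whole (global mean 0, sd
#' 1), and an entry is `TRUE` when its standardized value exceeds 0, i.e.
#' the gene's expression in that cell type exceeds the whole-matrix mean.
#'
#' @param profiles Non-negative genes x cell-type matrix; duplicate column
#'   names are treated as replicates.
#' @return Logical genes x cell-type matrix.
#' @export
immunopanning_boolean <- function(profiles) {
  if (any(profiles < 0)) stop("expression profiles must be non-negative")
  cts <- unique(colnames(profiles))
  if (is.null(cts)) stop("profiles need cell-type column names")
  avg <- vapply(cts, function(ct)
    rowMeans(profiles[, colnames(profiles) == ct, drop = FALSE]),
    numeric(nrow(profiles)))
  rownames(avg) <- rownames(profiles)
  lg <- log2(avg + 1)
  s <- stats::sd(as.vector(lg))
  if (s == 0) return(matrix(FALSE, nrow(lg), ncol(lg), dimnames = dimnames(lg)))
  (lg - mean(lg)) / s > 0
}

#' Boolean cell-type specificity from single-cell counts
#'
#' All-zero cells (columns) are dropped first. For each gene the overall
#' mean across retained cells and the per-cell-type mean are computed; an
#' entry is `TRUE` when the cell-type mean is at least
#' \code{fc_threshold} times the overall mean. Genes with overall mean 0
#' are `FALSE` everywhere.
#'
#' @param counts genes x cells non-negative matrix.
#' @param cell_labels Character vector (length = ncol) or named vector
#'   mapping cell -> cell type.
#' @param fc_threshold Fold-change threshold (default 3).
#' @return Logical genes x cell-type matrix.
#' @export
singlecell_boolean <- function(counts, cell_labels, fc_threshold = 3) {
  if (!is.null(names(cell_labels))) cell_labels <- cell_labels[colnames(counts)]
  if (length(cell_labels) != ncol(counts))
    stop("cell_labels must cover every cell column")
  nonzero <- colSums(counts) > 0
  if (!all(nonzero)) {
    counts <- counts[, nonzero, drop = FALSE]
    cell_labels <- cell_labels[nonzero]
  }
  cts <- unique(as.character(cell_labels))
  empty <- cts[!cts %in% cell_labels]
  if (length(empty) > 0) {
    warning("cell type(s) with no cells after filtering dropped: ",
            paste(empty, collapse = ", "))
    cts <- setdiff(cts, empty)
  }
  overall <- rowMeans(counts)
  type_means <- vapply(cts, function(ct)
    rowMeans(counts[, cell_labels == ct, drop = FALSE]),
    numeric(nrow(counts)))
  out <- type_means >= fc_threshold * overall & overall > 0
  dimnames(out) <- list(rownames(counts), cts)
  out
}

#' Overlap Fisher test with marker exclusion
#'
#' One-sided Fisher exact test of the overlap between a prediction gene set
#' and a reference-positive gene set within a background, after removing a
#' set of known markers from all three sets (so that marker genes cannot
#' inflate the agreement).
#'
#' @param pred_genes,reference_positive,background,exclude Character
#'   vectors of gene ids.
#' @return List with `overlap`, `pred_size`, `reference_size`,
#'   `background_size`, `p`.
#' @export
overlap_test <- function(pred_genes, reference_positive, background,
                         exclude = character(0)) {
  background <- setdiff(unique(background), exclude)
  pred <- setdiff(intersect(unique(pred_genes), background), exclude)
  ref <- setdiff(intersect(unique(reference_positive), background), exclude)
  if (length(pred) == 0) {
    warning("empty prediction set after marker exclusion; p = 1")
    return(list(overlap = 0L, pred_size = 0L, reference_size = length(ref),
                background_size = length(background), p = 1))
  }
  ft <- marker_fisher(pred, ref, background)
  list(overlap = ft$overlap, pred_size = ft$module_size,
       reference_size = ft$marker_size, background_size = length(background),
       p = ft$p_raw)
}

#' Bootstrap expression-specificity enrichment
#'
#' Tests whether a target gene list is more specific to a cell type than
#' random gene lists of the same length: the statistic is the mean
#' specificity of the target genes in the chosen column, the null is the
#' same statistic over `n_boot` uniform random gene sets drawn from the
#' specificity matrix rows, and the p-value is
#' \eqn{(1 + \#\{null \ge observed\}) / (n_{boot} + 1)}.
#'
#' @param target Character vector of gene ids; genes absent from the
#'   specificity matrix are dropped with a message.
#' @param specificity genes x cell-type numeric matrix (rows typically sum
#'   to 1).
#' @param cell_type Column to test.
#' @param n_boot Number of bootstrap draws (default 10000).
#' @param seed Integer seed.
#' @return List with `p`, `observed`, `null_mean`, `null_sd`, `n_used`.
#' @export
bootstrap_enrichment <- function(target, specificity, cell_type,
                                 n_boot = 10000, seed = 1) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!cell_type %in% colnames(specificity))
    stop("cell type '", cell_type, "' not in specificity matrix")
  keep <- intersect(unique(target), rownames(specificity))
  dropped <- length(unique(target)) - length(keep)
  if (dropped > 0) message(dropped, " target gene(s) absent from the specificity matrix dropped")
  if (length(keep) == 0) stop("no target genes left after filtering")
  col <- specificity[, cell_type]
  obs <- mean(col[keep])
  m <- length(keep)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- vapply(seq_len(n_boot),
                 function(i) mean(col[sample.int(length(col), m)]),
                 numeric(1))
  p <- (1 + sum(null >= obs)) / (n_boot + 1)
  list(p = p, observed = obs, null_mean = mean(null), null_sd = stats::sd(null),
       n_used = m)
}

#' Phenotype-term coverage and fold-change enrichment
#'
#' For each annotation term, coverage is the fraction of module genes
#' annotated with it; terms below \code{min_coverage} are dropped, and the
#' fold change compares the module coverage with the background rate:
#' \eqn{FC = (|module \cap term| / |module|) / (|background \cap term| /
#' |background|)}.
#'
#' @param module_genes Character vector of module gene ids.
#' @param term_annotations Named list term -> gene ids.
#' @param background Character vector: the gene universe.
#' @param min_coverage Minimum module coverage to report a term
#'   (default 0.02).
#' @return data.frame with `term`, `coverage`, `fold_change`, sorted by
#'   decreasing fold change.
#' @export
hpo_enrichment <- function(module_genes, term_annotations, background,
                           min_coverage = 0.02) {
  module_genes <- unique(module_genes)
  background <- unique(background)
  if (length(module_genes) == 0 || length(background) == 0)
    stop("module and background must be non-empty")
  rows <- list()
  for (term in names(term_annotations)) {
    bg_hits <- length(intersect(term_annotations[[term]], background))
    if (bg_hits == 0) next
    cov <- length(intersect(term_annotations[[term]], module_genes)) /
      length(module_genes)
    if (cov < min_coverage) next
    fc <- cov / (bg_hits / length(background))
    rows[[term]] <- data.frame(term = term, coverage = cov, fold_change = fc,
                               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(term = character(0), coverage = numeric(0),
                      fold_change = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$fold_change), ]
  rownames(out) <- NULL
  out
}
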