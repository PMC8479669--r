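GENE_STATES <- c("activated", "deactivated", "multifunctional",
                 "strongly_typed", "strongly_non_typed")

#' Extract <gene, cell type, function> triplets from an annotated network
#'
#' Every gene of a cell-type-enriched module yields one triplet carrying the
#' module's enriched cell type, the module's function terms (possibly empty)
#' and the gene's module membership; genes in non-enriched modules and
#' unassigned genes yield none.
#'
#' @param network `coexpression_network`.
#' @param module_celltypes Named vector module -> cell type.
#' @param function_annotations Optional named list module -> character
#'   vector of function terms (e.g. from
#'   \code{\link{annotate_module_functions}}).
#' @return data.frame with columns `gene`, `cell_type`, `functions`
#'   (semicolon-joined, may be ""), `network` (provenance), `module`, `mm`.
#' @export
extract_triplets <- function(network, module_celltypes,
                             function_annotations = NULL) {
  stopifnot(inherits(network, "coexpression_network"))
  rows <- list()
  for (m in names(module_celltypes)) {
    genes <- names(network$assignment)[network$assignment == m]
    if (length(genes) == 0) next
    terms <- if (!is.null(function_annotations) && m %in% names(function_annotations))
      paste(function_annotations[[m]], collapse = ";") else ""
    mm <- if (!is.null(network$membership) && m %in% colnames(network$membership))
      network$membership[genes, m] else rep(NA_real_, length(genes))
    rows[[m]] <- data.frame(gene = genes,
                            cell_type = module_celltypes[[m]],
                            functions = terms,
                            network = network$provenance,
                            module = m,
                            mm = unname(mm),
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), cell_type = character(0),
                      functions = character(0), network = character(0),
                      module = character(0), mm = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a gene's primary-to-secondary network transition
#'
#' Total function of the pair (primary cell type, secondary cell type),
#' where `NA` means the gene's module is not cell-type enriched:
#' (NA, type) is `activated`, (type, NA) `deactivated`, two different types
#' `multifunctional`, the same type twice `strongly_typed`, and (NA, NA)
#' `strongly_non_typed`. Vectorized over both arguments.
#'
#' @param primary_type,secondary_type Character vectors (or `NA`) of equal
#'   length.
#' @return Character vector of states.
#' @export
classify_transition <- function(primary_type, secondary_type) {
  n <- max(length(primary_type), length(secondary_type))
  p <- rep_len(as.character(primary_type), n)
  s <- rep_len(as.character(secondary_type), n)
  out <- character(n)
  out[is.na(p) & !is.na(s)] <- "activated"
  out[!is.na(p) & is.na(s)] <- "deactivated"
  out[!is.na(p) & !is.na(s) & p != s] <- "multifunctional"
  out[!is.na(p) & !is.na(s) & p == s] <- "strongly_typed"
  out[is.na(p) & is.na(s)] <- "strongly_non_typed"
  out
}

# per-gene cell type under one network+mapping; NA when not enriched
gene_types <- function(network, module_celltypes) {
  mod <- network$assignment
  ct <- rep(NA_character_, length(mod))
  hit <- mod %in% names(module_celltypes)
  ct[hit] <- unname(module_celltypes[mod[hit]])
  stats::setNames(ct, names(mod))
}

#' Aggregate gene states over the primary and all secondary networks
#'
#' Builds the per-gene, per-secondary-network transition states and the
#' aggregate annotation: a gene is `typed` when it sits in a cell-type
#' enriched module of the primary or any secondary network;
#' `multifunctional_any` when at least one secondary network moves it to a
#' module enriched for a different cell type than its primary one; and
#' `cell_types` is the union of all cell types assigned to it.
#'
#' @param pgcn Primary `coexpression_network`.
#' @param pgcn_mapping Named vector module -> cell type for the primary.
#' @param sgcns Named list cell type -> `coexpression_network`.
#' @param sgcn_mappings Named list cell type -> (module -> cell type) for
#'   each secondary network.
#' @return List with `states` (data.frame: `gene`, `primary_type`, one
#'   `state_<cell type>` column per secondary network, `typed`,
#'   `multifunctional_any`, `cell_types` semicolon-joined) and `summary`
#'   (named numeric vector of gene-pool fractions: per-cell-type typed
#'   fractions and `non_typed` from the primary network, `typed_pgcn`,
#'   `typed_after`, `gain`, `multifunctional_any`, `activated_any`,
#'   `deactivated_any`).
#' @export
aggregate_states <- function(pgcn, pgcn_mapping, sgcns = list(),
                             sgcn_mappings = list()) {
  genes <- names(pgcn$assignment)
  primary <- gene_types(pgcn, pgcn_mapping)
  df <- data.frame(gene = genes, primary_type = unname(primary),
                   stringsAsFactors = FALSE)
  ct_sets <- lapply(primary, function(x) if (is.na(x)) character(0) else x)
  names(ct_sets) <- genes
  mf_any <- stats::setNames(rep(FALSE, length(genes)), genes)
  act_any <- mf_any; deact_any <- mf_any
  for (ct in names(sgcns)) {
    sg <- sgcns[[ct]]
    sgenes <- names(sg$assignment)
    if (!setequal(sgenes, genes))
      stop("gene pools differ between primary and secondary '", ct, "' (",
           length(union(sgenes, genes)) - length(intersect(sgenes, genes)),
           " genes in the symmetric difference)")
    sec <- gene_types(sg, sgcn_mappings[[ct]])[genes]
    st <- classify_transition(primary, sec)
    df[[paste0("state_", ct)]] <- st
    mf_any <- mf_any | st == "multifunctional"
    act_any <- act_any | st == "activated"
    deact_any <- deact_any | st == "deactivated"
    for (g in genes[!is.na(sec)]) ct_sets[[g]] <- union(ct_sets[[g]], sec[[g]])
  }
  typed <- vapply(ct_sets, function(x) length(x) > 0, logical(1))
  df$typed <- unname(typed[genes])
  df$multifunctional_any <- unname(mf_any[genes])
  df$cell_types <- vapply(ct_sets[genes], function(x)
    paste(sort(x), collapse = ";"), "")
  pool <- length(genes)
  typed_pgcn <- sum(!is.na(primary))
  prim_frac <- table(factor(primary, levels = sort(unique(stats::na.omit(primary))))) / pool
  summary <- c(as.numeric(prim_frac),
               non_typed = (pool - typed_pgcn) / pool,
               typed_pgcn = typed_pgcn / pool,
               typed_after = sum(typed) / pool,
               gain = (sum(typed) - typed_pgcn) / pool,
               multifunctional_any = sum(mf_any) / pool,
               activated_any = sum(act_any) / pool,
               deactivated_any = sum(deact_any) / pool)
  if (length(prim_frac) > 0)
    names(summary)[seq_along(prim_frac)] <- paste0("typed_", names(prim_frac))
  list(states = df, summary = summary)
}
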