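#' Default run configuration
#'
#' Returns the default configuration list for \code{\link{run_gmsca}}:
#' minimum module size 100, 50 refinement iterations, automatic soft-power
#' selection, unsigned adjacency, enrichment alpha 0.05 with module-size
#' adjustment, 90\% variance target with tail dropping for signal removal,
#' and a master seed of 1.
#'
#' @param ... Named overrides merged over the defaults.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    expression = NULL, covariates = NULL, markers = NULL,
    functions = NULL, phenotypes = NULL,
    min_module_size = 100, max_kmeans_iter = 50, power = "auto",
    network_type = "unsigned", fit_threshold = 0.80, reassign_floor = 0.3,
    alpha = 0.05, variance_target = 0.90, tail = "drop",
    seed = 1, out = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full multifunctionality analysis
#'
#' Orchestrates the whole pipeline: read (or take) the expression matrix,
#' optionally regress out covariates, build the primary co-expression
#' network, annotate its modules with cell types, build one secondary
#' network per enriched cell type after principal-component signal removal,
#' annotate the secondary networks the same way, and classify every gene's
#' primary-to-secondary transitions. All artifacts are written under
#' `config$out` when set, together with a JSON manifest carrying the seed,
#' parameters, summary fractions and md5 checksums of the written files.
#'
#' @param config List from \code{\link{default_config}} (or a YAML file
#'   path with the same fields). `expression` and `markers` may be file
#'   paths, or an expression matrix and a named marker list respectively.
#' @return List with `pgcn`, `pgcn_enrichment`, `sgcns`,
#'   `sgcn_enrichments`, `triplets` (all networks combined), `states`,
#'   `summary`, `manifest`.
#' @export
run_gmsca <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  }
  stopifnot(is.list(config))
  config <- utils::modifyList(default_config(), config)
  seed <- as.integer(config$seed)

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      if (!is.null(config$out)) {
        dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
        writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                   file.path(config$out, "FAILED"))
      }
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  expr <- stage("preprocess", function() {
    e <- config$expression
    if (is.null(e)) stop("config$expression is required")
    if (is.character(e)) e <- read_expression(e)
    validate_expression(e)
    if (!is.null(config$covariates)) {
      cov <- config$covariates
      if (is.character(cov)) cov <- read_covariates(cov)
      e <- residualize(e, cov)
    }
    drop_constant_genes(e)
  })

  markers <- stage("enrichment", function() {
    mk <- config$markers
    if (is.null(mk)) stop("config$markers is required")
    if (is.character(mk) && length(mk) == 1) {
      if (!file.exists(mk)) stop("markers file not found: ", mk)
      mk <- read_gmt(mk)
    }
    mk
  })

  net_args <- list(
    power = if (identical(config$power, "auto")) NULL else as.integer(config$power),
    fit_threshold = config$fit_threshold, network_type = config$network_type,
    min_module_size = config$min_module_size,
    max_kmeans_iter = config$max_kmeans_iter,
    reassign_floor = config$reassign_floor)

  pgcn <- stage("gcn", function()
    do.call(build_network, c(list(expr = expr, provenance = "primary"), net_args)))
  pgcn_enr <- stage("enrichment", function()
    assign_cell_types(pgcn, markers, alpha = config$alpha))

  functions <- NULL
  if (!is.null(config$functions)) {
    fn <- config$functions
    if (is.character(fn) && length(fn) == 1) fn <- read_gmt(fn)
    functions <- fn
  }
  pgcn_fun <- if (!is.null(functions))
    annotate_module_functions(pgcn, functions, alpha = config$alpha) else NULL

  sgcns <- list(); sgcn_enr <- list(); sgcn_fun <- list()
  if (length(pgcn_enr$mapping) > 0) {
    sgcns <- stage("secondary", function()
      do.call(build_all_secondary,
              c(list(expr = expr, network = pgcn,
                     module_celltypes = pgcn_enr$mapping,
                     variance_target = config$variance_target,
                     tail = config$tail), net_args)))
    for (ct in names(sgcns)) {
      sgcn_enr[[ct]] <- stage("enrichment", function()
        assign_cell_types(sgcns[[ct]], markers, alpha = config$alpha))
      if (!is.null(functions))
        sgcn_fun[[ct]] <- annotate_module_functions(sgcns[[ct]], functions,
                                                    alpha = config$alpha)
    }
  } else {
    warning("no enriched cell types in the primary network; no secondary networks")
  }

  res <- stage("classify", function() {
    triplets <- extract_triplets(pgcn, pgcn_enr$mapping, pgcn_fun)
    for (ct in names(sgcns)) {
      triplets <- rbind(triplets,
                        extract_triplets(sgcns[[ct]], sgcn_enr[[ct]]$mapping,
                                         sgcn_fun[[ct]]))
    }
    agg <- aggregate_states(pgcn, pgcn_enr$mapping, sgcns,
                            lapply(sgcn_enr, `[[`, "mapping"))
    list(triplets = triplets, states = agg$states, summary = agg$summary)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("gmsca")),
    seed = seed,
    params = config[c("min_module_size", "max_kmeans_iter", "power",
                      "network_type", "fit_threshold", "reassign_floor",
                      "alpha", "variance_target", "tail")],
    soft_power_primary = pgcn$soft_power,
    n_genes = nrow(expr), n_samples = ncol(expr),
    n_modules_primary = length(setdiff(unique(pgcn$assignment), UNASSIGNED)),
    enriched_cell_types = as.list(pgcn_enr$mapping),
    n_secondary_networks = length(sgcns),
    n_triplets = nrow(res$triplets),
    summary = as.list(res$summary))

  if (!is.null(config$out)) {
    out <- config$out
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_network(pgcn, file.path(out, "pgcn"))
    utils::write.table(pgcn_enr$table, file.path(out, "pgcn_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (ct in names(sgcns)) {
      write_network(sgcns[[ct]], file.path(out, paste0("sgcn_", ct)))
      utils::write.table(sgcn_enr[[ct]]$table,
                         file.path(out, paste0("sgcn_", ct, "_enrichment.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep <- attr(sgcns[[ct]], "removal_reports")
      if (!is.null(rep))
        utils::write.table(rep,
                           file.path(out, paste0("sgcn_", ct, "_removal.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(res$triplets, file.path(out, "triplets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$states, file.path(out, "gene_states.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- setdiff(list.files(out, recursive = TRUE),
                     c("manifest.json", "FAILED"))
    sums <- tools::md5sum(file.path(out, files))
    manifest$checksums <- as.list(stats::setNames(unname(sums), files))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(pgcn = pgcn, pgcn_enrichment = pgcn_enr, sgcns = sgcns,
       sgcn_enrichments = sgcn_enr, triplets = res$triplets,
       states = res$states, summary = res$summary, manifest = manifest)
}
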