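#' Read a gene expression matrix from delimited text
#'
#' Reads a tab- or comma-delimited table (delimiter chosen from the file
#' extension: `.csv` means comma, anything else tab) with one header row and
#' one leading identifier column, and returns a numeric genes x samples
#' matrix with gene ids as row names and sample ids as column names.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param orientation `"genes_in_rows"` (default) if rows are genes, or
#'   `"samples_in_rows"` if rows are samples; the result is always
#'   genes x samples.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(data.frame(gene = c("G1", "G2"), S1 = c(1, 2), S2 = c(3, 4)),
#'             tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' read_expression(tf)
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(raw) < 2) stop("expected an identifier column plus at least one data column in ", path)
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate identifiers in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                               dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(m) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric value at row '", rownames(m)[bad[1, 1]],
         "', column '", colnames(m)[bad[1, 2]], "' in ", path)
  }
  if (orientation == "samples_in_rows") m <- t(m)
  validate_expression(m)
  m
}

#' Read a sample covariate table
#'
#' @param path Delimited text with a header and a leading sample-id column.
#'   Numeric-looking columns become numeric; the rest become factors.
#' @return data.frame with sample ids as row names.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  cov <- raw[, -1, drop = FALSE]
  for (j in seq_along(cov)) {
    if (!is.numeric(cov[[j]])) cov[[j]] <- factor(cov[[j]])
  }
  rownames(cov) <- ids
  cov
}

# Shared checks for the genes x samples container used throughout.
validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 genes and 2 samples")
  if (anyNA(m)) {
    na_rows <- rownames(m)[apply(is.na(m), 1, any)]
    stop("missing values in expression matrix (genes: ",
         paste(utils::head(na_rows, 5), collapse = ", "),
         if (length(na_rows) > 5) ", ..." else "", ")")
  }
  invisible(m)
}

#' Drop genes with zero variance across samples
#'
#' Constant genes carry no co-expression signal and break correlation-based
#' steps; they are removed with a warning naming how many were dropped.
#'
#' @param expr genes x samples numeric matrix.
#' @return The matrix without constant rows.
#' @export
drop_constant_genes <- function(expr) {
  validate_expression(expr)
  v <- apply(expr, 1, stats::var)
  keep <- v > 0
  if (!all(keep)) {
    warning("dropped ", sum(!keep), " zero-variance gene(s): ",
            paste(utils::head(rownames(expr)[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ..." else "")
    expr <- expr[keep, , drop = FALSE]
  }
  expr
}

#' Regress sample covariates out of every gene
#'
#' Fits, for each gene independently, an ordinary least squares model of its
#' expression on an intercept plus all covariate columns (categorical
#' covariates expanded to treatment-coded indicators) and returns the matrix
#' of residuals. Co-expression networks are then built from these residuals,
#' so that age, sex, RIN, PMI and similar technical or demographic effects do
#' not masquerade as co-expression.
#'
#' @param expr genes x samples numeric matrix.
#' @param cov data.frame of covariates with sample ids as row names; the
#'   sample set must equal the expression matrix's columns.
#' @return Matrix of the same shape; each row is the OLS residual vector
#'   (zero mean, zero sample correlation with every covariate column).
#' @export
residualize <- function(expr, cov) {
  validate_expression(expr)
  if (!is.data.frame(cov)) stop("cov must be a data.frame with sample row names")
  if (!setequal(rownames(cov), colnames(expr)))
    stop("covariate sample ids do not match expression sample ids")
  cov <- cov[colnames(expr), , drop = FALSE]
  for (j in seq_along(cov)) {
    if (is.factor(cov[[j]]) && nlevels(droplevels(cov[[j]])) < 2)
      stop("categorical covariate '", names(cov)[j], "' has fewer than 2 levels")
  }
  X <- stats::model.matrix(~ ., data = cov)
  if (ncol(expr) <= ncol(X))
    stop("need more samples (", ncol(expr), ") than design columns (", ncol(X), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  # residual of every gene at once: E - E Q Q'
  Q <- qr.Q(qrX)
  res <- expr - (expr %*% Q) %*% t(Q)
  dimnames(res) <- dimnames(expr)
  res
}
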