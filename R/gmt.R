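#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated gene-set format: one set per line, fields are
#' set name, description, then gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids; the `description`
#'   attribute holds each set's description field.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3
  if (any(short))
    stop("malformed GMT line(s) ", paste(which(short), collapse = ", "),
         " in ", path, " (need name, description, >=1 gene)")
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions;
#'   defaults to the set name.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
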