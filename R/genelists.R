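#' Load external gene lists
#'
#' Reads newline-delimited gene-symbol files (one symbol per line, `#`
#' comments allowed). Symbols are trimmed and upper-cased, duplicates
#' collapsed, empty lines skipped. An empty file yields an empty set with a
#' warning.
#'
#' @param paths named character vector or list, source name -> file path.
#' @return named list: source name -> character vector of symbols.
#' @export
load_gene_lists <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop_validation("paths must be named by source")
  out <- lapply(seq_along(paths), function(i) {
    path <- paths[[i]]
    if (!file.exists(path)) stop_io("gene list not readable: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    sym <- toupper(trimws(lines))
    sym <- unique(sym[sym != ""])
    if (length(sym) == 0L)
      warning("empty gene list: ", path, call. = FALSE)
    sort(sym)
  })
  names(out) <- names(paths)
  out
}

#' Validate a gene set against external autism gene lists
#'
#' Partitions the query genes into those found in the union of the validation
#' sources ("known") and those absent from all of them ("novel"), and records
#' the per-source intersections. Matching is exact after case-folding to
#' upper case; no alias or synonym resolution is attempted.
#'
#' @param query character vector of gene symbols.
#' @param sources named list of gene sets, e.g. from [load_gene_lists()].
#' @param name optional label for the query set.
#' @return object of class `validation_report`: list with `name`, `query`,
#'   `known`, `novel`, `per_source` (named list), and `counts`
#'   (`n_query`, `n_known`, `n_novel`).
#' @export
validate_genes <- function(query, sources, name = NULL) {
  if (length(sources) == 0L) stop_validation("at least one source is required")
  query <- sort(unique(toupper(trimws(query))))
  sources <- lapply(sources, function(s) toupper(trimws(s)))
  union_src <- sort(unique(unlist(sources, use.names = FALSE)))
  known <- intersect(query, union_src)
  structure(
    list(name = name,
         query = query,
         known = known,
         novel = setdiff(query, known),
         per_source = lapply(sources, function(s) intersect(query, s)),
         counts = c(n_query = length(query), n_known = length(known),
                    n_novel = length(query) - length(known))),
    class = "validation_report")
}

#' @exportS3Method base::print
print.validation_report <- function(x, ...) {
  cat(sprintf("Gene-set validation%s: %d genes, novel n = %d, known n = %d\n",
              if (is.null(x$name)) "" else paste0(" [", x$name, "]"),
              x$counts[["n_query"]], x$counts[["n_novel"]], x$counts[["n_known"]]))
  for (src in names(x$per_source))
    cat(sprintf("  %s: %d\n", src, length(x$per_source[[src]])))
  invisible(x)
}
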