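# Internal helpers: classed conditions, seeded evaluation, small assertions.

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("rg_validation_error", "rg_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("rg_io_error", "rg_error")))
}

stop_computation <- function(...) {
  stop(errorCondition(paste0(...), class = c("rg_computation_error", "rg_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' seeded package internals never perturb the user's random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is_count(seed)) stop_validation("seed must be a single non-negative integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Cheap deterministic checksum of a config list, used in provenance headers.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_lines <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("riskgrader"))
  out <- sprintf("# riskgrader %s", ver)
  if (!is.null(seed)) out <- c(out, sprintf("# seed=%d", as.integer(seed)))
  if (!is.null(config)) out <- c(out, sprintf("# config_hash=%s", config_hash(config)))
  out
}

# Write a data.frame as TSV with leading provenance comment lines.
write_tsv_prov <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_lines(seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
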