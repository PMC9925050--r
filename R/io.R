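#' Read and write trial tables
#'
#' Trial tables serialize as plain CSV with the canonical columns
#' (`participant` if present, `condition`, `value`, `soa_ms`, `rt_ms`,
#' `outcome`); values round-trip exactly at full precision.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `read_trials` the trial table; `write_trials` the path,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a DV-difference trace set or comparison table as CSV
#'
#' @param x Data frame (trace set, CAF table, bolus table, or comparison
#'   table).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write quantile summaries as JSON
#'
#' @param qs A `quantile_summary`.
#' @param path File path.
#' @return `read_quantile_summary` a `quantile_summary`;
#'   `write_quantile_summary` the path, invisibly.
#' @export
write_quantile_summary <- function(qs, path) {
  jsonlite::write_json(unclass(qs), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_quantile_summary
#' @export
read_quantile_summary <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    quantiles = as.data.frame(raw$quantiles, stringsAsFactors = FALSE),
    outcomes = as.data.frame(raw$outcomes, stringsAsFactors = FALSE),
    N = as.data.frame(raw$N, stringsAsFactors = FALSE),
    probs = raw$probs
  ), class = "quantile_summary")
}

#' Run manifest
#'
#' Writes a JSON manifest capturing what produced a set of outputs: the
#' seeds, settings and package version, sufficient to reproduce the run
#' byte-for-byte on the same platform (all randomness in the package is
#' seed-driven; no wall-clock defaults exist).
#'
#' @param path File path.
#' @param ... Named fields to record (seeds, settings lists, file names).
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, ...) {
  fields <- list(...)
  fields$package_version <- as.character(utils::packageVersion("valuerace"))
  fields$r_version <- R.version.string
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
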