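#' Read and write time-series matrices as TSV
#'
#' Series are stored as tab-separated text with one header row of node
#' names and one row per time point — the interchange format used
#' throughout the package for both continuous and +1/-1 series.
#'
#' @param series A matrix or data frame (rows = time points).
#' @param path File path.
#' @return `write_series_tsv()` returns `path` invisibly;
#'   `read_series_tsv()` returns a tibble.
#' @export
write_series_tsv <- function(series, path) {
  df <- tibble::as_tibble(as_numeric_matrix(series), .name_repair = "minimal")
  if (is.null(colnames(series))) {
    names(df) <- paste0("node_", seq_len(ncol(df)))
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and write model parameters as JSON
#'
#' Parameters are serialized as `{"h": [...], "J": [[...]], "order": ...}`.
#'
#' @param params A [mem_params] object.
#' @param path File path.
#' @return `write_params_json()` returns `path` invisibly;
#'   `read_params_json()` returns a [mem_params].
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "mem_params"))
  jsonlite::write_json(
    list(h = params$h, J = params$J, order = params$order),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mem_params(h = x$h, J = x$J, order = x$order)
}

write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(results$indices, file.path(out_dir, "indices.tsv"), progress = FALSE)
  readr::write_tsv(results$comparisons, file.path(out_dir, "comparisons.tsv"), progress = FALSE)
  readr::write_tsv(results$correlations, file.path(out_dir, "correlations.tsv"), progress = FALSE)
  readr::write_tsv(results$failures, file.path(out_dir, "failures.tsv"), progress = FALSE)
  cfg <- results$config
  jsonlite::write_json(
    cfg[!vapply(cfg, is.null, logical(1))],
    file.path(out_dir, "config.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(out_dir)
}
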