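#' Batch energy-landscape analysis over a manifest of inputs
#'
#' Drives the full analysis over a table of inputs. Each manifest row names
#' one subject or trial, its route and group; the per-input analysis
#' produces a pair of Gini polarization indices ([subject_indices()],
#' layer-averaged for the hidden-state route), after which every pair of
#' groups is compared on both indices (Bonferroni-corrected over all tests
#' performed) and index-score correlations are computed where behavioral
#' scores are present.
#'
#' @param manifest A data frame with one row per input:
#'   * `id` — unique input id (character).
#'   * `route` — `"binary"` (data already +1/-1), `"brain"` (continuous
#'     T x 9, binarized via [binarize_brain_route()]) or `"llm"` (a list of
#'     per-layer continuous matrices run through [per_layer_series()]).
#'   * `data` — list-column of matrices/data frames (for `llm`, a list of
#'     layer matrices), or alternatively `path` — TSV file path(s) read
#'     with [read_series_tsv()] (for `llm`, a directory of `layer_*.tsv`).
#'   * `group` — group label for comparisons.
#'   * optional `fluency`, `comprehension` — behavioral scores; `fluency`
#'     is correlated with the dwelling-time Gini and `comprehension` with
#'     the transition-frequency Gini, within each group.
#' @param config A [pipeline_config()]; input `i` uses walk seed
#'   `config$seed + i` (and layer seeds offset from it).
#' @param out_dir Optional directory; when given, results are written as
#'   TSV (`indices.tsv`, `comparisons.tsv`, `correlations.tsv`,
#'   `failures.tsv`) plus `config.json`.
#' @return A list of class `elscape_results`: `indices`, `comparisons`,
#'   `correlations`, `failures` tibbles and the `config`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir = NULL) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1L)
  if (!all(c("id", "route", "group") %in% names(manifest))) {
    rlang::abort("Manifest needs columns `id`, `route`, `group` (+ `data` or `path`).")
  }
  rows <- vector("list", nrow(manifest))
  fails <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    res <- tryCatch(
      analyze_input(row, cfg_i),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- tibble::tibble(
        id = as.character(row$id), error = conditionMessage(res)
      )
    } else {
      rows[[i]] <- dplyr::bind_cols(
        tibble::tibble(id = as.character(row$id), route = row$route,
                       group = row$group),
        res
      )
    }
  }
  indices <- dplyr::bind_rows(rows)
  failures <- dplyr::bind_rows(fails)
  if (nrow(failures)) {
    rlang::warn(sprintf("%d input(s) failed and were skipped.", nrow(failures)))
  }
  comparisons <- group_comparisons(indices)
  correlations <- behavior_correlations(manifest, indices)
  out <- structure(
    list(
      indices = indices, comparisons = comparisons,
      correlations = correlations, failures = failures, config = config
    ),
    class = "elscape_results"
  )
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

analyze_input <- function(row, config) {
  data <- if ("data" %in% names(row) && !is.null(row$data[[1L]])) {
    row$data[[1L]]
  } else if ("path" %in% names(row)) {
    load_input(row$path, row$route)
  } else {
    rlang::abort("Manifest row has neither `data` nor `path`.")
  }
  route <- as.character(row$route)
  if (route == "binary") {
    subject_indices(data, config)
  } else if (route == "brain") {
    series <- binarize_brain_route(data, threshold_mode = config$threshold_mode)
    subject_indices(series, config)
  } else if (route == "llm") {
    layer_list <- per_layer_series(
      data,
      window_start = config$window_start, window_end = config$window_end,
      k = config$k, seed = config$seed, restarts = config$restarts
    )
    per_layer <- purrr::imap(layer_list, function(b, nm) {
      cfg_l <- config
      cfg_l$seed <- config$seed + attr(b, "layer") * 131L
      dplyr::mutate(subject_indices(b, cfg_l), layer = attr(b, "layer"))
    })
    layer_average(dplyr::bind_rows(per_layer))
  } else {
    rlang::abort(sprintf("Unknown route '%s'.", route))
  }
}

load_input <- function(path, route) {
  path <- as.character(path)
  if (route == "llm" && dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^layer_.*\\.tsv$", full.names = TRUE))
    if (length(files) < 2L) rlang::abort(sprintf("No layer TSVs found under %s.", path))
    lapply(files, read_series_tsv)
  } else {
    read_series_tsv(path)
  }
}

group_comparisons <- function(indices) {
  empty <- tibble::tibble(
    index = character(), group_a = character(), group_b = character(),
    t = numeric(), df = numeric(), p = numeric(), p_bonferroni = numeric(),
    eta_sq = numeric(), n_a = integer(), n_b = integer()
  )
  if (nrow(indices) == 0L) return(empty)
  groups <- sort(unique(indices$group))
  if (length(groups) < 2L) return(empty)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  tests <- list()
  for (pr in pairs) {
    for (idx in c("gini_dwell", "gini_trans")) {
      a <- indices[[idx]][indices$group == pr[1]]
      b <- indices[[idx]][indices$group == pr[2]]
      if (length(a) < 2L || length(b) < 2L) next
      tests[[length(tests) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(index = idx, group_a = pr[1], group_b = pr[2]),
        compare_groups(a, b, n_comparisons = 1L)
      )
    }
  }
  if (length(tests) == 0L) return(empty)
  out <- dplyr::bind_rows(tests)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

behavior_correlations <- function(manifest, indices) {
  empty <- tibble::tibble(
    group = character(), index = character(), score = character(),
    r = numeric(), n = integer(), p = numeric(), undefined = logical()
  )
  score_map <- c(fluency = "gini_dwell", comprehension = "gini_trans")
  present <- intersect(names(score_map), names(manifest))
  if (length(present) == 0L || nrow(indices) == 0L) return(empty)
  joined <- dplyr::left_join(
    indices,
    dplyr::mutate(
      manifest[, c("id", present), drop = FALSE],
      id = as.character(id)
    ),
    by = "id"
  )
  out <- list()
  for (sc in present) {
    idx <- score_map[[sc]]
    for (g in sort(unique(joined$group))) {
      sub <- joined[joined$group == g & !is.na(joined[[sc]]), ]
      if (nrow(sub) < 3L) next
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(group = g, index = idx, score = sc),
        correlate_with_behavior(sub[[idx]], sub[[sc]])
      )
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}

#' @export
print.elscape_results <- function(x, ...) {
  cat(sprintf(
    "<elscape_results> %d inputs analyzed (%d failed), %d group tests, %d correlations\n",
    nrow(x$indices), nrow(x$failures), nrow(x$comparisons), nrow(x$correlations)
  ))
  invisible(x)
}
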