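#' Binarize network-averaged brain-like recordings
#'
#' Converts a continuous T x 9 matrix of network-averaged signals into a
#' +1/-1 state series using the whole-recording average signal as the
#' threshold: by default node `i` at time `t` is +1 iff its signal strictly
#' exceeds the across-node average signal at `t` (ties give -1). The
#' alternative reading of "average signal as a threshold" — each node
#' against its own temporal mean — is available via `threshold_mode`.
#'
#' @param series A T x 9 continuous matrix or data frame, no missing values.
#' @param threshold_mode `"per_timepoint_global_mean"` (default) or
#'   `"per_node_temporal_mean"`.
#' @return A T x 9 tibble of +1/-1 activities with the input column names
#'   (or `node_1..node_9`).
#' @examples
#' binarize_brain_route(matrix(c(rep(1, 8), 10), nrow = 1))
#' @export
binarize_brain_route <- function(series,
                                 threshold_mode = c("per_timepoint_global_mean",
                                                    "per_node_temporal_mean")) {
  threshold_mode <- rlang::arg_match(threshold_mode)
  X <- as_numeric_matrix(series)
  if (ncol(X) != 9L) {
    rlang::abort(sprintf(
      "Brain-route series must have exactly 9 columns (networks); got %d.", ncol(X)
    ))
  }
  check_no_missing(X)
  thr <- switch(threshold_mode,
    per_timepoint_global_mean = rowMeans(X),
    per_node_temporal_mean = {
      out <- matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
      out
    }
  )
  out <- ifelse(X > thr, 1, -1)
  colnames(out) <- colnames(series) %||% paste0("node_", seq_len(9L))
  tibble::as_tibble(out)
}

as_numeric_matrix <- function(x, arg = "series") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    rlang::abort(sprintf("`%s` must be a numeric matrix or data frame.", arg))
  }
  x
}

check_no_missing <- function(X) {
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    rlang::abort(sprintf(
      "Series contains missing/non-finite values at rows {%s}, columns {%s}.",
      paste(unique(bad[, 1])[1:min(5, length(unique(bad[, 1])))], collapse = ", "),
      paste(unique(bad[, 2]), collapse = ", ")
    ))
  }
  invisible(X)
}

#' Select the analyzed iteration window of a hidden-state series
#'
#' Keeps the rows in the half-open window `[window_start, window_end)` of
#' the 0-based iteration axis, discarding early iterations (dominated by
#' the input prompt) and late ones (where fluctuations die out). The
#' defaults keep iterations 1e4 to 6e4.
#'
#' @param series A continuous matrix or data frame (rows = iterations).
#' @param window_start,window_end 0-based half-open window bounds; must
#'   satisfy `0 <= window_start < window_end <= nrow(series)`.
#' @return The windowed series, same type columns, as a tibble.
#' @export
select_iteration_window <- function(series, window_start = 1e4,
                                    window_end = 6e4) {
  X <- as_numeric_matrix(series)
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  if (window_start < 0L || window_start >= window_end ||
      window_end > nrow(X)) {
    rlang::abort(sprintf(
      "Window [%d, %d) must lie within the %d iterations and be non-empty.",
      window_start, window_end, nrow(X)
    ))
  }
  out <- X[(window_start + 1L):window_end, , drop = FALSE]
  if (is.null(colnames(out))) colnames(out) <- paste0("col_", seq_len(ncol(out)))
  tibble::as_tibble(out)
}

#' Cluster observed nodes into k groups by their time courses
#'
#' Each column is z-normalized over time (constant columns become all-zero
#' and are reported), then the columns are partitioned with k-means
#' (squared-Euclidean distance on the normalized time courses), keeping the
#' best of `restarts` random initializations by within-cluster sum of
#' squares. Deterministic given `seed`.
#'
#' @param series A T x n_hidden continuous matrix or data frame.
#' @param k Number of clusters (default 9).
#' @param seed Integer seed for the k-means initializations.
#' @param restarts Number of k-means++ initializations (default 10); the
#'   partition with the lowest within-cluster sum of squares wins.
#' @return An object of class `cluster_assignment`: tibble with columns
#'   `column`, `cluster` (1..k) and attributes `k`, `sizes`, `tot_withinss`.
#' @export
cluster_nodes <- function(series, k = 9L, seed = 1L, restarts = 10L) {
  X <- as_numeric_matrix(series)
  check_no_missing(X)
  if (ncol(X) < k) {
    rlang::abort(sprintf(
      "Need at least k = %d columns to form %d clusters; got %d.", k, k, ncol(X)
    ))
  }
  Z <- scale(X)
  const <- which(attr(Z, "scaled:scale") == 0 | !is.finite(attr(Z, "scaled:scale")))
  if (length(const)) {
    rlang::inform(sprintf(
      "%d constant column(s) normalized to all-zero: %s",
      length(const), paste(utils::head(const, 5), collapse = ", ")
    ))
    Z[, const] <- 0
  }
  pts <- t(Z)
  km <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- pts[kmeanspp_centers(pts, k), , drop = FALSE]
      fit <- suppressWarnings(
        stats::kmeans(pts, centers = centers, iter.max = 200L)
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  out <- tibble::tibble(
    column = colnames(X) %||% paste0("col_", seq_len(ncol(X))),
    cluster = as.integer(km$cluster)
  )
  attr(out, "k") <- as.integer(k)
  attr(out, "sizes") <- as.integer(km$size)
  attr(out, "tot_withinss") <- km$tot.withinss
  class(out) <- c("cluster_assignment", class(out))
  out
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance from the nearest chosen one.
# Robust on tightly clumped duplicated channels, where uniformly random
# starting centers routinely miss a clump.
kmeanspp_centers <- function(pts, k) {
  n <- nrow(pts)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(pts, 2, pts[idx[1], ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      idx[j + 1L] <- sample.int(n, 1L)
    } else {
      idx[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(pts, 2, pts[idx[j + 1L], ])^2))
  }
  idx
}

#' Reduce columns to cluster means and binarize
#'
#' Averages the member columns of each cluster at every time point, then
#' thresholds each cluster-mean time course at its own temporal average:
#' +1 iff strictly above, else -1.
#'
#' @param series The continuous matrix the clustering was computed on
#'   (same columns).
#' @param clusters A [cluster_nodes()] result (or tibble with `cluster`
#'   integer per column, in column order).
#' @return A T x k tibble of +1/-1 activities, columns `node_1..node_k`
#'   ordered by cluster id.
#' @export
reduce_and_binarize <- function(series, clusters) {
  X <- as_numeric_matrix(series)
  cl <- clusters$cluster
  if (length(cl) != ncol(X)) {
    rlang::abort("Cluster assignment does not cover every column of the series.")
  }
  k <- max(cl)
  if (!setequal(unique(cl), seq_len(k))) {
    rlang::abort("Empty cluster id encountered; clusters must be 1..k, all non-empty.")
  }
  means <- vapply(
    seq_len(k),
    function(g) rowMeans(X[, cl == g, drop = FALSE]),
    numeric(nrow(X))
  )
  if (nrow(X) == 1L) means <- matrix(means, nrow = 1L)
  out <- ifelse(sweep(means, 2, colMeans(means), `-`) > 0, 1, -1)
  colnames(out) <- paste0("node_", seq_len(k))
  tibble::as_tibble(out)
}

#' Per-layer preprocessing of stacked hidden-state recordings
#'
#' Applies the full hidden-state route — iteration-window selection, k-means
#' clustering of nodes, cluster-mean binarization — to each layer
#' separately. The first layer is excluded (its states merely represent the
#' input tokens), so the result covers layers `2..n_layers`.
#'
#' @param layers A list of continuous matrices, one per layer, in layer
#'   order (layer 1 first).
#' @param window_start,window_end Passed to [select_iteration_window()];
#'   `NULL` keeps all iterations.
#' @param k,seed,restarts Passed to [cluster_nodes()]; each layer uses seed
#'   `seed + layer`.
#' @return A named list (`layer_2`, ...) of T x k +1/-1 tibbles, each with
#'   attribute `layer`.
#' @export
per_layer_series <- function(layers, window_start = NULL, window_end = NULL,
                             k = 9L, seed = 1L, restarts = 10L) {
  if (!is.list(layers) || length(layers) < 2L) {
    rlang::abort("Need at least 2 layers (the first is excluded from analysis).")
  }
  keep <- 2:length(layers)
  out <- lapply(keep, function(l) {
    X <- as_numeric_matrix(layers[[l]])
    if (!is.null(window_start)) {
      X <- as.matrix(select_iteration_window(X, window_start, window_end))
    }
    cl <- cluster_nodes(X, k = k, seed = seed + l, restarts = restarts)
    b <- reduce_and_binarize(X, cl)
    attr(b, "layer") <- l
    b
  })
  names(out) <- paste0("layer_", keep)
  out
}

#' Best cluster-label matching against a reference assignment
#'
#' Finds the permutation of cluster labels maximizing agreement with a
#' reference map (exact assignment by bitmask dynamic programming, k <= 12)
#' and reports the achieved agreement fraction. Used to score clustering
#' recovery on synthetic data where the true column-to-cluster map is known.
#'
#' @param assignment A [cluster_nodes()] result or integer vector of cluster
#'   labels per column.
#' @param truth Integer vector of true cluster ids per column (same order).
#' @return A list with `agreement` (fraction of columns matched), `mapping`
#'   (named integer vector: estimated label -> reference label).
#' @export
match_clusters <- function(assignment, truth) {
  est <- if (is.data.frame(assignment)) assignment$cluster else as.integer(assignment)
  truth <- as.integer(truth)
  stopifnot(length(est) == length(truth))
  k1 <- max(est)
  k2 <- max(truth)
  k <- max(k1, k2)
  if (k > 12L) rlang::abort("Exact label matching supported up to k = 12.")
  conf <- matrix(0L, k, k)
  for (i in seq_along(est)) conf[est[i], truth[i]] <- conf[est[i], truth[i]] + 1L
  # DP over subsets of reference labels: best[mask + 1] = max agreement using
  # the first popcount(mask) estimated labels matched to reference set `mask`
  n_mask <- bitwShiftL(1L, k)
  best <- rep(-1L, n_mask)
  choice <- rep(NA_integer_, n_mask)
  prev <- rep(NA_integer_, n_mask)
  best[1L] <- 0L
  popcount <- vapply(0:(n_mask - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1L))) > 0L), integer(1))
  for (mask in 0:(n_mask - 2L)) {
    if (best[mask + 1L] < 0L) next
    row <- popcount[mask + 1L] + 1L
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) > 0L) next
      nxt <- bitwOr(mask, bit)
      val <- best[mask + 1L] + conf[row, j]
      if (val > best[nxt + 1L]) {
        best[nxt + 1L] <- val
        choice[nxt + 1L] <- j
        prev[nxt + 1L] <- mask
      }
    }
  }
  mapping <- integer(k)
  mask <- n_mask - 1L
  while (mask > 0L) {
    j <- choice[mask + 1L]
    mapping[popcount[mask + 1L]] <- j
    mask <- prev[mask + 1L]
  }
  names(mapping) <- as.character(seq_len(k))
  list(
    agreement = best[n_mask] / length(est),
    mapping = mapping
  )
}
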