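#' All activity patterns of an N-node binary system
#'
#' Enumerates the `2^N` activity patterns as a matrix of +1/-1 entries.
#' Pattern `k` (0-based state index, row `k + 1`) encodes node `i` in bit
#' `i - 1` of `k`: the bit is 1 iff `sigma_i = +1`, with node 1 the least
#' significant bit. This indexing is used consistently across the package
#' (state tables, basin maps, trajectories).
#'
#' @param n_nodes Number of nodes `N` (at most 16).
#' @return A `2^N x N` matrix with entries -1/+1.
#' @examples
#' state_patterns(2)
#' @export
state_patterns <- function(n_nodes) {
  check_enumerable(n_nodes)
  k <- 0:(2^n_nodes - 1L)
  m <- vapply(
    seq_len(n_nodes),
    function(i) ifelse(bitwAnd(k, bitwShiftL(1L, i - 1L)) > 0L, 1, -1),
    numeric(length(k))
  )
  colnames(m) <- paste0("node_", seq_len(n_nodes))
  m
}

#' 0-based state index of +1/-1 patterns
#'
#' Inverse of the row order of [state_patterns()].
#'
#' @param patterns A +1/-1 vector, or a matrix/data frame with one pattern
#'   per row.
#' @return Integer vector of 0-based state indices.
#' @export
state_index <- function(patterns) {
  x <- as_pm1_matrix(patterns)
  bits <- (x + 1L) / 2L
  as.integer(bits %*% bitwShiftL(1L, seq_len(ncol(x)) - 1L))
}

check_enumerable <- function(n_nodes, max_nodes = 16L) {
  if (n_nodes > max_nodes) {
    rlang::abort(sprintf(
      "N = %d nodes is too large for exhaustive enumeration of 2^N states (limit %d).",
      n_nodes, max_nodes
    ))
  }
  invisible(n_nodes)
}

# Coerce a series/pattern to a +1/-1 numeric matrix, validating entries.
as_pm1_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  if (anyNA(x) || !all(x %in% c(-1, 1))) {
    rlang::abort(sprintf("`%s` must contain only +1/-1 entries.", arg))
  }
  unname(x)
}

#' Energy of activity patterns under a maximum-entropy model
#'
#' Computes `E(V) = -sum_i h_i sigma_i - (1/2) sum_ij J_ij sigma_i sigma_j`
#' for one pattern or for every row of a pattern matrix.
#'
#' @param pattern A +1/-1 vector of length `N`, or a matrix with one pattern
#'   per row.
#' @param params A [mem_params] object.
#' @return A numeric scalar (single pattern) or vector (one energy per row).
#' @examples
#' p <- mem_params(h = c(1, -1), J = matrix(c(0, 0.5, 0.5, 0), 2))
#' state_energy(c(1, 1), p)  # -(1 - 1) - 0.5 = -0.5
#' @export
state_energy <- function(pattern, params) {
  stopifnot(inherits(params, "mem_params"))
  S <- as_pm1_matrix(pattern, "pattern")
  if (ncol(S) != params$n_nodes) {
    rlang::abort(sprintf(
      "Pattern has %d nodes but the model has %d.", ncol(S), params$n_nodes
    ))
  }
  e <- -as.vector(S %*% params$h) - 0.5 * rowSums((S %*% params$J) * S)
  if (nrow(S) == 1L && is.null(dim(pattern))) e[[1L]] else e
}

#' Exact Boltzmann distribution over all 2^N states
#'
#' Enumerates every activity pattern, computes its energy and its
#' probability `P(V_k) = exp(-E(V_k)) / sum_l exp(-E(V_l))`. The
#' normalization is numerically stabilized by shifting all energies by the
#' minimum before exponentiating.
#'
#' @param params A [mem_params] object with at most 16 nodes.
#' @return A tibble of class `mem_state_table` with columns `state` (0-based
#'   index), `energy` and `prob`, plus attributes `patterns` (the
#'   [state_patterns()] matrix) and `params`.
#' @examples
#' tab <- exact_distribution(mem_params(h = rep(0, 3)))
#' all.equal(tab$prob, rep(1 / 8, 8))
#' @export
exact_distribution <- function(params) {
  stopifnot(inherits(params, "mem_params"))
  n <- params$n_nodes
  check_enumerable(n)
  S <- state_patterns(n)
  e <- state_energy(S, params)
  w <- exp(-(e - min(e)))
  out <- tibble::tibble(
    state = 0:(2^n - 1L),
    energy = e,
    prob = w / sum(w)
  )
  attr(out, "patterns") <- S
  attr(out, "params") <- params
  class(out) <- c("mem_state_table", class(out))
  out
}

# Internal: recover the pattern matrix attached to a state table (or rebuild).
table_patterns <- function(table) {
  p <- attr(table, "patterns")
  if (is.null(p)) p <- state_patterns(as.integer(round(log2(nrow(table)))))
  p
}

# Internal: neighbor state matrix. Entry [k + 1, i] is the 1-based row of the
# state obtained from state k by flipping node i (Hamming-1 adjacency).
neighbor_matrix <- function(n_nodes) {
  k <- 0:(2^n_nodes - 1L)
  vapply(
    seq_len(n_nodes),
    function(i) bitwXor(k, bitwShiftL(1L, i - 1L)) + 1L,
    integer(length(k))
  )
}
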