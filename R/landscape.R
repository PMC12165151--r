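#' Local minima of an energy landscape
#'
#' Scans all `2^N` states of a [exact_distribution()] table against their
#' `N` Hamming-1 neighbors (two patterns are adjacent iff they differ at
#' exactly one node). A state is a local minimum when its energy is strictly
#' smaller than every neighbor's.
#'
#' @param table A `mem_state_table` from [exact_distribution()].
#' @return A tibble of class `energy_minima` with one row per minimum:
#'   `minimum` (1-based id, in state-index order), `state` (0-based state
#'   index) and `energy`.
#' @export
find_local_minima <- function(table) {
  stopifnot(inherits(table, "mem_state_table"))
  e <- table$energy
  n <- as.integer(round(log2(length(e))))
  nb <- neighbor_matrix(n)
  nb_min <- matrix(e[nb], nrow = nrow(nb))
  nb_min <- do.call(pmin, as.data.frame(nb_min))
  is_min <- e < nb_min
  out <- tibble::tibble(
    minimum = seq_len(sum(is_min)),
    state = table$state[is_min],
    energy = e[is_min]
  )
  class(out) <- c("energy_minima", class(out))
  out
}

#' Assign every state to an attractor basin
#'
#' From each state, energy descent iterates to the lowest-energy strictly
#' smaller neighbor (ties between equally low neighbors broken toward the
#' lowest state index) until a local minimum is reached; the reached minimum
#' is the state's attractor. States whose lowest descending neighbors are
#' tied between neighbors that themselves descend to different minima are
#' flagged as saddles; they are still assigned deterministically by the
#' tie-break.
#'
#' @param table A `mem_state_table`.
#' @param minima The matching [find_local_minima()] result.
#' @return A tibble of class `basin_map` with columns `state`, `energy`,
#'   `minimum` (id of the attractor reached), `basin_state` (its state
#'   index), `is_minimum` and `saddle`.
#' @export
assign_basins <- function(table, minima) {
  stopifnot(inherits(table, "mem_state_table"), inherits(minima, "energy_minima"))
  e <- table$energy
  m <- length(e)
  n <- as.integer(round(log2(m)))
  nb <- neighbor_matrix(n)
  nbe <- matrix(e[nb], nrow = m)
  low <- do.call(pmin, as.data.frame(nbe))
  descend <- low < e
  target <- seq_len(m)
  tie_count <- integer(m)
  for (k in which(descend)) {
    cand <- nb[k, nbe[k, ] == low[k]]
    tie_count[k] <- length(cand)
    target[k] <- min(cand)
  }
  # pointer jumping: minima are fixed points of `target`
  repeat {
    nxt <- target[target]
    if (identical(nxt, target)) break
    target <- nxt
  }
  basin_state <- table$state[target]
  min_id <- match(basin_state, minima$state)
  if (anyNA(min_id)) rlang::abort("Descent reached a non-minimum; minima and table disagree.")
  saddle <- logical(m)
  cand_rows <- which(descend & tie_count >= 2L)
  for (k in cand_rows) {
    cand <- nb[k, nbe[k, ] == low[k]]
    saddle[k] <- length(unique(min_id[cand])) >= 2L
  }
  out <- tibble::tibble(
    state = table$state,
    energy = e,
    minimum = as.integer(min_id),
    basin_state = basin_state,
    is_minimum = table$state %in% minima$state,
    saddle = saddle
  )
  class(out) <- c("basin_map", class(out))
  out
}

#' Disconnectivity tree of the local minima
#'
#' Implements the threshold-lowering construction: starting from the highest
#' energy value, vertices above a threshold `E_threshold` are removed and
#' one checks which local minima remain connected; the merge energy of two
#' minima is the smallest threshold at which a path of vertices with energy
#' `<= E_threshold` still joins them. Equivalently (and as implemented,
#' bottom-up with union-find over states added in increasing energy order,
#' energy ties broken by state index), it is the minimax barrier: the
#' minimum over Hamming paths of the maximum vertex energy en route.
#'
#' @param table A `mem_state_table`.
#' @param minima The matching [find_local_minima()] result (>= 1 minimum).
#' @return An object of class `disconnectivity`: a list with `leaves` (the
#'   minima tibble), `merge` (an hclust-style merge matrix; negative entries
#'   index leaves, positive entries earlier merges) and `height` (the merge
#'   energies, non-decreasing). A single minimum yields zero merges.
#' @export
build_disconnectivity <- function(table, minima) {
  stopifnot(inherits(table, "mem_state_table"), inherits(minima, "energy_minima"))
  if (nrow(minima) < 1L) rlang::abort("Need at least one local minimum.")
  e <- table$energy
  m <- length(e)
  n <- as.integer(round(log2(m)))
  nb <- neighbor_matrix(n)
  ord <- order(e, table$state)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # tree node id carried by each union-find root: -leaf for minima,
  # +merge index for internal vertices, 0 for components without minima
  node_of <- integer(m)
  leaf_of_state <- integer(m)
  leaf_of_state[minima$state + 1L] <- seq_len(nrow(minima))
  added <- logical(m)
  merges <- matrix(0L, nrow = max(nrow(minima) - 1L, 0L), ncol = 2L)
  heights <- numeric(nrow(merges))
  n_merge <- 0L
  for (v in ord) {
    added[v] <- TRUE
    if (leaf_of_state[v] > 0L) node_of[v] <- -leaf_of_state[v]
    for (w in nb[v, ]) {
      if (!added[w]) next
      rv <- find(v); rw <- find(w)
      if (rv == rw) next
      nv <- node_of[rv]; nw <- node_of[rw]
      if (nv != 0L && nw != 0L) {
        n_merge <- n_merge + 1L
        merges[n_merge, ] <- c(nv, nw)
        heights[n_merge] <- e[v]
        parent[rw] <- rv
        node_of[rv] <- n_merge
      } else {
        parent[rw] <- rv
        node_of[rv] <- if (nv != 0L) nv else nw
      }
    }
    if (n_merge == nrow(minima) - 1L) break
  }
  structure(
    list(leaves = minima, merge = merges, height = heights),
    class = "disconnectivity"
  )
}

#' @export
print.disconnectivity <- function(x, ...) {
  cat(sprintf(
    "<disconnectivity> %d local minima, %d merges\n",
    nrow(x$leaves), length(x$height)
  ))
  if (length(x$height)) {
    cat("  merge energies:", paste(signif(x$height, 4), collapse = " "), "\n")
  }
  invisible(x)
}

#' Pairwise merge energies between local minima
#'
#' @param tree A [build_disconnectivity()] result.
#' @return A symmetric M x M matrix; entry (a, b) is the energy threshold at
#'   which minima a and b disconnect (diagonal `NA`).
#' @export
merge_energies <- function(tree) {
  stopifnot(inherits(tree, "disconnectivity"))
  m <- nrow(tree$leaves)
  out <- matrix(NA_real_, m, m)
  members <- lapply(seq_len(m), identity)
  for (i in seq_along(tree$height)) {
    kids <- lapply(tree$merge[i, ], function(id) {
      if (id < 0L) id * -1L else members[[m + id]]
    })
    for (a in kids[[1]]) for (b in kids[[2]]) {
      out[a, b] <- out[b, a] <- tree$height[i]
    }
    members[[m + i]] <- c(kids[[1]], kids[[2]])
  }
  out
}

#' Depth of each attractor basin
#'
#' The depth of a minimum is the energy barrier it must overcome to reach a
#' lower minimum: the merge level of the disconnectivity tree at which its
#' subtree first joins a subtree containing a strictly lower minimum
#' (exact energy ties broken by state index), minus the minimum's own
#' energy. The overall lowest minimum escapes only at the root, so its
#' depth is root height minus its energy. With a single minimum the depth
#' is `NA`.
#'
#' @param tree A [build_disconnectivity()] result.
#' @return A tibble with `minimum`, `state`, `energy`, `merge_energy` (the
#'   escape level) and `depth`.
#' @export
basin_depths <- function(tree) {
  stopifnot(inherits(tree, "disconnectivity"))
  leaves <- tree$leaves
  m <- nrow(leaves)
  escape <- rep(NA_real_, m)
  better <- function(i, j) {
    leaves$energy[i] < leaves$energy[j] ||
      (leaves$energy[i] == leaves$energy[j] && leaves$state[i] < leaves$state[j])
  }
  if (length(tree$height)) {
    members <- lapply(seq_len(m), identity)
    for (i in seq_along(tree$height)) {
      kids <- lapply(tree$merge[i, ], function(id) {
        if (id < 0L) -id else members[[m + id]]
      })
      best <- lapply(kids, function(s) s[order(leaves$energy[s], leaves$state[s])[1]])
      for (side in 1:2) {
        rival <- best[[3 - side]]
        for (a in kids[[side]]) {
          if (is.na(escape[a]) && better(rival, a)) escape[a] <- tree$height[i]
        }
      }
      members[[m + i]] <- c(kids[[1]], kids[[2]])
    }
    root_best <- which(is.na(escape))
    escape[root_best] <- tree$height[length(tree$height)]
  }
  dplyr::mutate(
    tibble::as_tibble(leaves),
    merge_energy = escape,
    depth = escape - energy
  )
}

#' Newick serialization of a disconnectivity tree
#'
#' Branch lengths are energy differences between a node and its parent merge
#' level; internal node labels carry the merge energies, so standard tree
#' viewers reproduce the barrier structure.
#'
#' @param tree A [build_disconnectivity()] result.
#' @param digits Significant digits for energies.
#' @return A single Newick string (terminated by `;`).
#' @export
as_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "disconnectivity"))
  leaves <- tree$leaves
  render <- function(id, parent_height) {
    if (id < 0L) {
      k <- -id
      sprintf(
        "m%d_s%d:%s", k, leaves$state[k],
        format(parent_height - leaves$energy[k], digits = digits)
      )
    } else {
      h <- tree$height[id]
      sprintf(
        "(%s,%s)%s:%s",
        render(tree$merge[id, 1], h), render(tree$merge[id, 2], h),
        format(h, digits = digits),
        format(parent_height - h, digits = digits)
      )
    }
  }
  if (length(tree$height) == 0L) {
    return(sprintf("(m1_s%d:0);", leaves$state[1]))
  }
  root <- length(tree$height)
  h <- tree$height[root]
  sprintf(
    "(%s,%s)%s;",
    render(tree$merge[root, 1], h), render(tree$merge[root, 2], h),
    format(h, digits = digits)
  )
}
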