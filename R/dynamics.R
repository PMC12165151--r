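#' Metropolis-Hastings random walk on the energy landscape
#'
#' Starting from a uniformly random activity pattern, each step proposes one
#' of the `N` Hamming-1 neighbors uniformly and accepts the move with
#' probability `min(1, exp(E(V_i) - E(V_j)))`, so downhill moves are always
#' taken and uphill moves occasionally, which keeps the walk from being
#' trapped forever in one minimum. The stationary distribution of the chain
#' is the model's Boltzmann distribution. After discarding the first
#' `burn_in` patterns the visited states are mapped to their attractor
#' labels.
#'
#' @param table A `mem_state_table` from [exact_distribution()].
#' @param basins Optional [assign_basins()] result; when supplied the
#'   trajectory carries attractor labels.
#' @param n_steps Total number of patterns in the trajectory (default 1e5).
#' @param burn_in Number of initial patterns discarded (default 100).
#' @param seed Integer seed; fixed seed gives an identical trajectory.
#' @return An object of class `walk_trajectory`: list with `states` (0-based
#'   state indices, length `n_steps - burn_in`), `labels` (attractor ids or
#'   `NULL`), `n_steps`, `burn_in`, `seed`.
#' @export
random_walk <- function(table, basins = NULL, n_steps = 1e5, burn_in = 100,
                        seed = 1L) {
  stopifnot(inherits(table, "mem_state_table"))
  n_steps <- as.integer(n_steps)
  burn_in <- as.integer(burn_in)
  if (burn_in >= n_steps) rlang::abort("`burn_in` must be smaller than `n_steps`.")
  e <- table$energy
  m <- length(e)
  n <- as.integer(round(log2(m)))
  nb <- neighbor_matrix(n)
  acc <- pmin(exp(e - matrix(e[nb], nrow = m)), 1)
  states <- integer(n_steps)
  withr::with_seed(seed, {
    cur <- sample.int(m, 1L)
    picks <- sample.int(n, n_steps - 1L, replace = TRUE)
    u <- stats::runif(n_steps - 1L)
    states[1L] <- cur
    for (t in seq_len(n_steps - 1L)) {
      i <- picks[t]
      if (u[t] < acc[cur, i]) cur <- nb[cur, i]
      states[t + 1L] <- cur
    }
  })
  kept <- states[(burn_in + 1L):n_steps]
  labels <- NULL
  if (!is.null(basins)) {
    stopifnot(inherits(basins, "basin_map"))
    labels <- basins$minimum[kept]
  }
  structure(
    list(
      states = table$state[kept], labels = labels,
      n_steps = n_steps, burn_in = burn_in, seed = seed
    ),
    class = "walk_trajectory"
  )
}

#' @export
print.walk_trajectory <- function(x, ...) {
  cat(sprintf(
    "<walk_trajectory> %d retained steps (%d total, burn-in %d), seed %d\n",
    length(x$states), x$n_steps, x$burn_in, x$seed
  ))
  if (!is.null(x$labels)) {
    cat("  attractors visited:", paste(sort(unique(x$labels)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Dwelling-time and transition-frequency summary of a trajectory
#'
#' Run-length encodes the attractor label sequence. The dwelling time of an
#' attractor is the mean length of its consecutive runs (its total occupancy
#' is reported alongside); the transition frequency of an unordered
#' attractor pair is the number of adjacent label changes between the two.
#'
#' @param traj A [random_walk()] result with attractor labels, or a plain
#'   vector of labels.
#' @return An object of class `dynamics_summary`: list with `dwell` (tibble
#'   `minimum`, `mean_dwell`, `occupancy`, `n_runs`), `transitions` (tibble
#'   `from`, `to` with `from < to`, `count`) and `n_steps` (trajectory
#'   length).
#' @examples
#' s <- summarize_dynamics(c(1, 1, 2))
#' s$dwell$mean_dwell   # 2, 1
#' s$transitions$count  # 1
#' @export
summarize_dynamics <- function(traj) {
  labels <- if (inherits(traj, "walk_trajectory")) traj$labels else traj
  if (is.null(labels) || length(labels) == 0L) {
    rlang::abort("Trajectory has no attractor labels to summarize.")
  }
  r <- rle(as.vector(labels))
  dwell <- tibble::tibble(minimum = r$values, len = r$lengths) |>
    dplyr::group_by(minimum) |>
    dplyr::summarise(
      mean_dwell = mean(len),
      occupancy = sum(len),
      n_runs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(minimum)
  v <- r$values
  if (length(v) > 1L) {
    a <- v[-length(v)]
    b <- v[-1L]
    transitions <- tibble::tibble(from = pmin(a, b), to = pmax(a, b)) |>
      dplyr::count(from, to, name = "count") |>
      dplyr::arrange(from, to)
  } else {
    transitions <- tibble::tibble(
      from = integer(), to = integer(), count = integer()
    )
  }
  structure(
    list(dwell = dwell, transitions = transitions, n_steps = length(labels)),
    class = "dynamics_summary"
  )
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf(
    "<dynamics_summary> %d steps, %d attractors visited, %d switch events\n",
    x$n_steps, nrow(x$dwell), sum(x$transitions$count)
  ))
  invisible(x)
}
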