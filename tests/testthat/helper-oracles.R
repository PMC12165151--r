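# Independent oracle implementations used to cross-check the package.
# These deliberately use naive loops / direct formulas, not the package's
# vectorized code paths.

# Energy by direct double loop over the displayed formula.
oracle_energy <- function(sigma, h, J) {
  n <- length(sigma)
  e <- 0
  for (i in seq_len(n)) {
    e <- e - h[i] * sigma[i]
    for (j in seq_len(n)) e <- e - 0.5 * J[i, j] * sigma[i] * sigma[j]
  }
  e
}

# All +/-1 patterns as rows, bit i of the 0-based index = node i.
oracle_patterns <- function(n) {
  S <- matrix(0, 2^n, n)
  for (k in 0:(2^n - 1)) {
    for (i in seq_len(n)) {
      S[k + 1, i] <- if (bitwAnd(k, 2^(i - 1)) > 0) 1 else -1
    }
  }
  S
}

# Exact Boltzmann moments by brute-force summation over all patterns.
oracle_moments <- function(h, J) {
  n <- length(h)
  S <- oracle_patterns(n)
  e <- apply(S, 1, oracle_energy, h = h, J = J)
  p <- exp(-e) / sum(exp(-e))
  first <- numeric(n)
  second <- matrix(0, n, n)
  for (k in seq_len(nrow(S))) {
    first <- first + S[k, ] * p[k]
    second <- second + outer(S[k, ], S[k, ]) * p[k]
  }
  list(first = first, second = second, prob = p, energy = e)
}

# Local minima by a direct scan: strictly smaller than all Hamming-1 neighbors.
oracle_minima <- function(energies) {
  n <- as.integer(round(log2(length(energies))))
  out <- integer(0)
  for (k in 0:(length(energies) - 1)) {
    nb_e <- sapply(seq_len(n), function(i) energies[bitwXor(k, 2^(i - 1)) + 1])
    if (all(energies[k + 1] < nb_e)) out <- c(out, k)
  }
  out
}

# Minimax path barrier between all state pairs on the hypercube:
# min over paths of the max vertex energy en route (endpoints included),
# by Floyd-Warshall on edge weights max(E_i, E_j).
oracle_minimax_barriers <- function(energies) {
  m <- length(energies)
  n <- as.integer(round(log2(m)))
  B <- matrix(Inf, m, m)
  for (k in 0:(m - 1)) {
    B[k + 1, k + 1] <- energies[k + 1]
    for (i in seq_len(n)) {
      j <- bitwXor(k, 2^(i - 1))
      B[k + 1, j + 1] <- max(energies[k + 1], energies[j + 1])
    }
  }
  for (v in seq_len(m)) {
    for (a in seq_len(m)) {
      for (b in seq_len(m)) {
        B[a, b] <- min(B[a, b], max(B[a, v], B[v, b]))
      }
    }
  }
  B
}

# Gini by the raw pairwise mean-absolute-difference definition.
oracle_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Random symmetric zero-diagonal coupling matrix + fields.
random_params <- function(n, seed, range = 0.5) {
  withr::with_seed(seed, {
    J <- matrix(0, n, n)
    J[upper.tri(J)] <- stats::runif(choose(n, 2), -range, range)
    mem_params(h = stats::runif(n, -range, range), J = J + t(J))
  })
}

# Set of minima reachable from `state` by strictly descending moves of any
# kind (not just steepest); used to certify basin assignments where the
# reachable minimum is unique.
oracle_reachable_minima <- function(energies, state) {
  n <- as.integer(round(log2(length(energies))))
  seen <- new.env()
  out <- integer(0)
  recurse <- function(k) {
    key <- as.character(k)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    nb <- sapply(seq_len(n), function(i) bitwXor(k, 2^(i - 1)))
    lower <- nb[energies[nb + 1] < energies[k + 1]]
    if (length(lower) == 0) {
      out <<- union(out, k)
    } else {
      for (w in lower) recurse(w)
    }
  }
  recurse(state)
  sort(out)
}

# Moments object with n_samples = Inf (no boundary shrinkage), for feeding
# hand-picked targets to the fitting functions.
new_moments_for_test <- function(first, second) {
  m <- empirical_moments(matrix(rep(c(1, -1), length(first)),
                                nrow = 2, byrow = TRUE))
  m$first <- as.numeric(first)
  m$second <- unname(as.matrix(second))
  m$n_samples <- Inf
  m
}
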