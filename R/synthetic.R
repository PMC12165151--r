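#' Exact i.i.d. sampling from a maximum-entropy model
#'
#' Draws each time point independently from the exact Boltzmann distribution
#' of `params`, computed by full `2^N` enumeration. This removes temporal
#' autocorrelation entirely, which makes it the cleanest generator for
#' moment-matching and parameter-recovery experiments; see
#' [sample_glauber_series()] for a temporally correlated alternative with
#' the same stationary law.
#'
#' @param params A [mem_params] object (N <= 16).
#' @param n_timepoints Number of rows T to draw.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return A T x N tibble of +1/-1 activities (columns `node_1..node_N`).
#' @export
sample_mem_series <- function(params, n_timepoints, seed = 1L) {
  stopifnot(inherits(params, "mem_params"), n_timepoints >= 1)
  tab <- exact_distribution(params)
  S <- table_patterns(tab)
  idx <- withr::with_seed(
    seed,
    sample.int(nrow(tab), n_timepoints, replace = TRUE, prob = tab$prob)
  )
  tibble::as_tibble(S[idx, , drop = FALSE])
}

#' Glauber (single-site heat-bath) sampling from a maximum-entropy model
#'
#' Runs a Markov chain that updates one uniformly chosen node per step,
#' setting it to +1 with probability `exp(a) / (exp(a) + exp(-a))` where
#' `a = h_i + sum_j J_ij sigma_j`. The chain's stationary distribution is
#' the Boltzmann distribution of `params`. With `thin = 1` consecutive
#' recorded rows differ in at most one node; larger `thin` records every
#' `thin`-th update, reducing autocorrelation.
#'
#' @inheritParams sample_mem_series
#' @param burn_in Number of initial single-site updates discarded.
#' @param thin Record every `thin`-th update (default 1).
#' @return A T x N tibble of +1/-1 activities.
#' @export
sample_glauber_series <- function(params, n_timepoints, seed = 1L,
                                  burn_in = 0L, thin = 1L) {
  stopifnot(inherits(params, "mem_params"), n_timepoints >= 1, thin >= 1)
  check_enumerable(params$n_nodes)
  n <- params$n_nodes
  h <- params$h
  J <- params$J
  total <- burn_in + n_timepoints * thin
  out <- matrix(0, n_timepoints, n)
  withr::with_seed(seed, {
    sigma <- sample(c(-1, 1), n, replace = TRUE)
    sites <- sample.int(n, total, replace = TRUE)
    u <- stats::runif(total)
    row <- 0L
    for (t in seq_len(total)) {
      i <- sites[t]
      a <- h[i] + sum(J[i, ] * sigma)
      sigma[i] <- if (u[t] < 1 / (1 + exp(-2 * a))) 1 else -1
      if (t > burn_in && (t - burn_in) %% thin == 0L) {
        row <- row + 1L
        out[row, ] <- sigma
      }
    }
  })
  colnames(out) <- paste0("node_", seq_len(n))
  tibble::as_tibble(out)
}

#' Model parameters for the two qualitative landscape regimes
#'
#' Constructs parameter sets whose exhaustive landscapes reproduce two
#' qualitative regimes. `uniform_shallow` partitions the nodes into equal
#' weak ferromagnetic blocks; every block can align either way, so the
#' landscape has many minima of similar, shallow depth. `polarized`
#' replaces the first block by a larger, strongly coupled one on top of the
#' same weak remainder, so deep and shallow minima coexist. Small Gaussian
#' jitter on all couplings breaks exact symmetries; draws are retried
#' (fresh jitter) until the landscape has at least two local minima.
#'
#' @param regime `"uniform_shallow"` or `"polarized"`.
#' @param n_nodes Number of nodes (default 9).
#' @param seed Integer seed; fixed seed gives identical parameters.
#' @param weak_coupling Within-block coupling of the weak blocks
#'   (default 0.3).
#' @param weak_block_size Size of the weak blocks (default 3).
#' @param block_size Number of nodes in the strong block of the polarized
#'   regime (default 4).
#' @param block_coupling Coupling strength inside the strong block
#'   (default 0.8).
#' @param jitter_sd Standard deviation of the symmetry-breaking jitter
#'   added to every off-diagonal coupling and to the fields,
#'   which also breaks the exact global spin-flip degeneracy (default 0.02).
#' @param max_retries Bounded number of re-draws when a landscape has fewer
#'   than two minima.
#' @return A [mem_params] object with attribute `regime`.
#' @export
make_regime_params <- function(regime = c("uniform_shallow", "polarized"),
                               n_nodes = 9L, seed = 1L,
                               weak_coupling = 0.3, weak_block_size = 3L,
                               block_size = 4L, block_coupling = 0.8,
                               jitter_sd = 0.02, max_retries = 20L) {
  regime <- rlang::arg_match(regime)
  stopifnot(n_nodes >= 2)
  check_enumerable(n_nodes)
  if (regime == "polarized" && block_size > n_nodes) {
    rlang::abort("`block_size` cannot exceed `n_nodes`.")
  }
  base <- matrix(0, n_nodes, n_nodes)
  first <- if (regime == "polarized") block_size else weak_block_size
  starts <- c(1L, seq(first + 1L, n_nodes, by = weak_block_size))
  for (b in seq_along(starts)) {
    lo <- starts[b]
    hi <- min(if (b == 1L) lo + first - 1L else lo + weak_block_size - 1L, n_nodes)
    base[lo:hi, lo:hi] <- if (b == 1L && regime == "polarized") {
      block_coupling
    } else {
      weak_coupling
    }
  }
  diag(base) <- 0
  for (try in seq_len(max_retries)) {
    params <- withr::with_seed(seed + (try - 1L) * 1009L, {
      jit <- matrix(0, n_nodes, n_nodes)
      jit[upper.tri(jit)] <- stats::rnorm(choose(n_nodes, 2), 0, jitter_sd)
      mem_params(
        h = stats::rnorm(n_nodes, 0, jitter_sd),
        J = base + jit + t(jit)
      )
    })
    minima <- find_local_minima(exact_distribution(params))
    if (nrow(minima) >= 2L) {
      attr(params, "regime") <- regime
      attr(params, "seed") <- seed
      return(params)
    }
  }
  rlang::abort(sprintf(
    "Could not obtain >= 2 local minima for regime '%s' after %d draws.",
    regime, max_retries
  ))
}

#' Emit noisy continuous observations from a latent binary series
#'
#' Emulates high-dimensional recordings in which many observed channels
#' track one latent network: each latent node is duplicated into
#' `nodes_per_cluster` observed columns, each column getting an independent
#' random gain, offset and Gaussian noise. The true column-to-cluster map is
#' returned alongside for downstream recovery checks.
#'
#' @param latent A T x N +1/-1 matrix or data frame (the latent series).
#' @param nodes_per_cluster Number of observed columns per latent node.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (arbitrary units, >= 0).
#' @param seed Integer seed.
#' @param gain_range,offset_range Ranges of the per-column uniform gain and
#'   offset draws; set to `c(1, 1)` and `c(0, 0)` for an identity emission.
#' @return An object of class `synthetic_observations`: list with `series`
#'   (T x N*nodes_per_cluster tibble), `cluster_map` (tibble `column`,
#'   `cluster`), `gains`, `offsets` and `latent`.
#' @export
emit_continuous_observations <- function(latent, nodes_per_cluster = 1L,
                                         noise_sd = 0.1, seed = 1L,
                                         gain_range = c(0.5, 1.5),
                                         offset_range = c(-1, 1)) {
  X <- as_pm1_matrix(latent, "latent")
  if (nodes_per_cluster < 1L) rlang::abort("`nodes_per_cluster` must be >= 1.")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be nonnegative.")
  n <- ncol(X)
  p <- n * nodes_per_cluster
  cluster <- rep(seq_len(n), each = nodes_per_cluster)
  obs <- withr::with_seed(seed, {
    gains <- stats::runif(p, gain_range[1], gain_range[2])
    offsets <- stats::runif(p, offset_range[1], offset_range[2])
    base <- X[, cluster, drop = FALSE]
    noise <- if (noise_sd > 0) {
      matrix(stats::rnorm(length(base), 0, noise_sd), nrow(base))
    } else 0
    list(
      series = sweep(sweep(base, 2, gains, `*`), 2, offsets, `+`) + noise,
      gains = gains, offsets = offsets
    )
  })
  series <- obs$series
  colnames(series) <- sprintf("ch_%03d", seq_len(p))
  structure(
    list(
      series = tibble::as_tibble(series),
      cluster_map = tibble::tibble(column = colnames(series), cluster = cluster),
      gains = obs$gains, offsets = obs$offsets,
      latent = X
    ),
    class = "synthetic_observations"
  )
}

#' @export
print.synthetic_observations <- function(x, ...) {
  cat(sprintf(
    "<synthetic_observations> %d timepoints x %d channels (%d latent clusters)\n",
    nrow(x$series), ncol(x$series), max(x$cluster_map$cluster)
  ))
  invisible(x)
}
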