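#' Configuration of the per-subject analysis pipeline
#'
#' Collects the tunable knobs of [subject_indices()] and [run_pipeline()].
#'
#' @param n_steps,burn_in Random-walk length and discarded prefix (defaults
#'   1e5 and 100).
#' @param seed Integer base seed for the walk.
#' @param dwell_stat Vector fed to the dwelling-time Gini: `"mean_run"`
#'   (mean consecutive run length per attractor, default) or `"occupancy"`
#'   (total steps per attractor).
#' @param include_zero_pairs Include unordered attractor pairs with zero
#'   switches (among visited attractors) in the transition vector
#'   (default TRUE).
#' @param learning_rate,tol,max_iter Passed to [fit_pairwise()].
#' @param threshold_mode Passed to [binarize_brain_route()] for brain-route
#'   inputs.
#' @param window_start,window_end,k,restarts Hidden-state route settings
#'   (see [per_layer_series()]); `window_start = NULL` keeps all rows.
#' @return A list of class `elscape_config`.
#' @export
pipeline_config <- function(n_steps = 1e5, burn_in = 100, seed = 1L,
                            dwell_stat = c("mean_run", "occupancy"),
                            include_zero_pairs = TRUE,
                            learning_rate = 0.2, tol = 1e-6, max_iter = 1e5,
                            threshold_mode = "per_timepoint_global_mean",
                            window_start = NULL, window_end = NULL,
                            k = 9L, restarts = 10L) {
  structure(
    list(
      n_steps = n_steps, burn_in = burn_in, seed = as.integer(seed),
      dwell_stat = rlang::arg_match(dwell_stat),
      include_zero_pairs = include_zero_pairs,
      learning_rate = learning_rate, tol = tol, max_iter = max_iter,
      threshold_mode = threshold_mode,
      window_start = window_start, window_end = window_end,
      k = as.integer(k), restarts = as.integer(restarts)
    ),
    class = "elscape_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(
      sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "elscape_stage_error", parent = e
    )
  })
}

#' Polarization indices of one subject or trial
#'
#' Runs the full per-input analysis on a binary state series: fits the
#' independent and pairwise maximum-entropy models, measures the fit
#' accuracy r_D, builds the energy landscape (minima, basins), simulates a
#' Metropolis-Hastings random walk, and condenses the walk into two Gini
#' coefficients — of the per-attractor dwelling times and of the pairwise
#' transition frequencies. Landscapes with a single attractor (or a walk
#' that visits only one) yield zero indices flagged undefined.
#'
#' @param series A T x 9 +1/-1 matrix or data frame.
#' @param config A [pipeline_config()].
#' @return A one-row tibble of class `polarization_indices`: `gini_dwell`,
#'   `gini_trans`, `undefined_dwell`, `undefined_trans`, `r_d`, `n_minima`,
#'   `n_visited`, `fit_iterations`, `seed`.
#' @export
subject_indices <- function(series, config = pipeline_config()) {
  stopifnot(inherits(config, "elscape_config"))
  X <- as_pm1_matrix(series, "series")
  moments <- with_stage("moments", empirical_moments(X))
  pairwise <- with_stage("fit_pairwise", fit_pairwise(
    moments,
    learning_rate = config$learning_rate,
    tol = config$tol, max_iter = config$max_iter
  ))
  independent <- with_stage("fit_independent", fit_independent(moments))
  acc <- with_stage("fit_accuracy", fit_accuracy(X, pairwise, independent))
  tab <- with_stage("landscape", exact_distribution(pairwise))
  minima <- with_stage("landscape", find_local_minima(tab))
  basins <- with_stage("landscape", assign_basins(tab, minima))
  walk <- with_stage("dynamics", random_walk(
    tab, basins,
    n_steps = config$n_steps, burn_in = config$burn_in, seed = config$seed
  ))
  dyn <- with_stage("dynamics", summarize_dynamics(walk))
  vecs <- polarization_vectors(dyn, config)
  g_dwell <- gini(vecs$dwell)
  g_trans <- gini(vecs$trans)
  out <- tibble::tibble(
    gini_dwell = as.numeric(g_dwell),
    gini_trans = as.numeric(g_trans),
    undefined_dwell = attr(g_dwell, "undefined"),
    undefined_trans = attr(g_trans, "undefined"),
    r_d = acc$r_d,
    n_minima = nrow(minima),
    n_visited = nrow(dyn$dwell),
    fit_iterations = attr(pairwise, "iterations"),
    seed = config$seed
  )
  class(out) <- c("polarization_indices", class(out))
  out
}

# Internal: the two nonnegative vectors the Gini step consumes.
polarization_vectors <- function(dyn, config) {
  dwell <- switch(config$dwell_stat,
    mean_run = dyn$dwell$mean_dwell,
    occupancy = dyn$dwell$occupancy
  )
  visited <- sort(dyn$dwell$minimum)
  if (length(visited) >= 2L && config$include_zero_pairs) {
    pairs <- t(utils::combn(visited, 2L))
    key <- paste(pairs[, 1], pairs[, 2])
    counts <- stats::setNames(
      rep(0, nrow(pairs)), key
    )
    obs_key <- paste(dyn$transitions$from, dyn$transitions$to)
    counts[obs_key] <- dyn$transitions$count
    trans <- as.numeric(counts)
  } else {
    trans <- as.numeric(dyn$transitions$count)
  }
  if (length(trans) == 0L) trans <- 0
  list(dwell = dwell, trans = trans)
}

#' Average polarization indices across layers
#'
#' Arithmetic mean of the dwelling-time and transition-frequency Gini
#' coefficients over layers with defined values; undefined layers are
#' reported and skipped.
#'
#' @param per_layer A tibble of per-layer [subject_indices()] rows (bind of
#'   one row per layer).
#' @return A one-row tibble with the averaged `gini_dwell`, `gini_trans`,
#'   `r_d` and the number of layers used per index.
#' @export
layer_average <- function(per_layer) {
  stopifnot(is.data.frame(per_layer), nrow(per_layer) >= 1L)
  ok_d <- !per_layer$undefined_dwell
  ok_t <- !per_layer$undefined_trans
  if (!any(ok_d) && !any(ok_t)) {
    rlang::abort("All layers have undefined indices; nothing to average.")
  }
  dropped <- sum(!ok_d | !ok_t)
  if (dropped > 0L) {
    rlang::inform(sprintf("%d layer(s) with undefined indices skipped.", dropped))
  }
  tibble::tibble(
    gini_dwell = mean(per_layer$gini_dwell[ok_d]),
    gini_trans = mean(per_layer$gini_trans[ok_t]),
    r_d = mean(per_layer$r_d, na.rm = TRUE),
    n_layers_dwell = sum(ok_d),
    n_layers_trans = sum(ok_t)
  )
}

#' Two-sample comparison of polarization indices between groups
#'
#' Two-sample t-test (pooled variance by default, Welch optional) with
#' Bonferroni correction over `n_comparisons` tests and the effect size
#' `eta^2 = t^2 / (t^2 + df)`.
#'
#' @param a,b Numeric index vectors for the two groups (each length >= 2).
#' @param n_comparisons Size of the Bonferroni family (default 1).
#' @param var_equal Pooled-variance t-test when TRUE (default); Welch
#'   otherwise.
#' @return A one-row tibble: `t`, `df`, `p`, `p_bonferroni`, `eta_sq`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, n_comparisons = 1L, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    rlang::abort("Both groups need at least 2 observations.")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    df <- if (var_equal) length(a) + length(b) - 2L else NA_real_
    tstat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    p <- if (tstat == 0) 1 else 0
    return(tibble::tibble(
      t = tstat, df = df, p = p,
      p_bonferroni = min(1, p * n_comparisons),
      eta_sq = if (tstat == 0) 0 else 1,
      n_a = length(a), n_b = length(b)
    ))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  tstat <- unname(ht$statistic)
  df <- unname(ht$parameter)
  tibble::tibble(
    t = tstat, df = df, p = ht$p.value,
    p_bonferroni = min(1, ht$p.value * n_comparisons),
    eta_sq = tstat^2 / (tstat^2 + df),
    n_a = length(a), n_b = length(b)
  )
}

#' Pearson correlation between polarization indices and behavioral scores
#'
#' @param indices,scores Numeric vectors of equal length >= 3.
#' @return A one-row tibble: `r`, `n`, `p`, `undefined` (TRUE when either
#'   vector is constant, in which case `r` and `p` are `NA`).
#' @export
correlate_with_behavior <- function(indices, scores) {
  x <- as.numeric(indices); y <- as.numeric(scores)
  if (length(x) != length(y) || length(x) < 3L) {
    rlang::abort("`indices` and `scores` must have equal length >= 3.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::inform("Constant vector: correlation undefined.")
    return(tibble::tibble(r = NA_real_, n = length(x), p = NA_real_, undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), n = length(x), p = ct$p.value, undefined = FALSE
  )
}
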