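#' Empirical first and second moments of a binary state series
#'
#' Time-averages `<sigma_i>` and `<sigma_i sigma_j>` of a T x N series of
#' +1/-1 activities. These are the sufficient statistics the maximum-entropy
#' fit matches.
#'
#' @param series A T x N matrix or data frame with entries +1/-1.
#' @return An object of class `mem_moments`: a list with `first` (length-N
#'   vector in \[-1, 1\]), `second` (symmetric N x N matrix with unit
#'   diagonal) and `n_samples` (T).
#' @examples
#' m <- empirical_moments(rbind(c(1, -1), c(-1, 1)))
#' m$first                 # c(0, 0)
#' m$second[1, 2]          # -1
#' @export
empirical_moments <- function(series) {
  X <- as_pm1_matrix(series, "series")
  if (nrow(X) < 1L) rlang::abort("`series` must have at least one time point.")
  new_mem_moments(
    first = colMeans(X),
    second = crossprod(X) / nrow(X),
    n_samples = nrow(X)
  )
}

new_mem_moments <- function(first, second, n_samples) {
  structure(
    list(first = as.numeric(first), second = unname(second), n_samples = n_samples),
    class = "mem_moments"
  )
}

#' Exact model moments of a maximum-entropy model
#'
#' `<sigma_i>_m = sum_k sigma_i(V_k) P(V_k)` and the matching second moments,
#' computed by exhaustive enumeration via [exact_distribution()]. The result
#' carries `n_samples = Inf`, so no boundary shrinkage is applied when it is
#' passed to a fitting function.
#'
#' @param params A [mem_params] object (N <= 16).
#' @return An object of class `mem_moments`.
#' @export
exact_moments <- function(params) {
  tab <- exact_distribution(params)
  m <- table_moments(tab)
  new_mem_moments(m$first, m$second, Inf)
}

# Internal: moments of a state table (patterns weighted by prob).
table_moments <- function(table) {
  S <- table_patterns(table)
  p <- table$prob
  list(
    first = as.vector(crossprod(S, p)),
    second = crossprod(S, S * p)
  )
}

#' @export
print.mem_moments <- function(x, ...) {
  cat(sprintf(
    "<mem_moments> N = %d nodes, n_samples = %s\n",
    length(x$first), format(x$n_samples)
  ))
  cat("  <sigma_i> in [", signif(min(x$first), 3), ",",
      signif(max(x$first), 3), "]\n")
  invisible(x)
}

# Internal: shrink moments toward 0 by n/(n + 1) so that boundary values
# (+/-1, which would need infinite parameters) become fittable. Exact moments
# (n_samples = Inf) pass through unchanged.
shrink_moments <- function(moments) {
  n <- moments$n_samples
  if (!is.finite(n)) return(moments)
  f <- n / (n + 1)
  at_boundary <- any(abs(moments$first) >= 1) ||
    any(abs(moments$second[upper.tri(moments$second)]) >= 1)
  if (at_boundary) {
    rlang::inform(
      "Some empirical moments sit at +/-1; shrinking by T/(T+1) keeps the fit finite."
    )
  }
  second <- moments$second * f
  diag(second) <- 1
  new_mem_moments(moments$first * f, second, n)
}
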