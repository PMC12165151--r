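#' Fit the pairwise maximum-entropy model by gradient ascent
#'
#' Adjusts `h` and `J` until the model moments, computed exactly by `2^N`
#' enumeration at every step, match the (shrunk) empirical moments. The
#' update is plain gradient ascent on the log-likelihood: the gradient with
#' respect to `h_i` is `<sigma_i> - <sigma_i>_m` and with respect to `J_ij`
#' is `<sigma_i sigma_j> - <sigma_i sigma_j>_m`. Iteration stops when the
#' largest absolute moment gap falls below `tol`.
#'
#' @param moments An `mem_moments` object, from [empirical_moments()] or
#'   [exact_moments()].
#' @param learning_rate Step size applied to both `h` and `J` updates.
#' @param tol Convergence tolerance on the maximum absolute moment gap
#'   (default 1e-6, tight enough that parameter error stays an order of
#'   magnitude below 1e-4 even on ill-conditioned moment sets).
#' @param max_iter Maximum number of gradient steps; exceeding it is an
#'   error that reports the final gap.
#' @return A fitted [mem_params] of order `"pairwise"`, with attributes
#'   `iterations`, `final_gap` and `converged`.
#' @examples
#' truth <- mem_params(h = c(0.3, -0.2), J = matrix(c(0, 0.4, 0.4, 0), 2))
#' fit <- fit_pairwise(exact_moments(truth))
#' max(abs(fit$h - truth$h))
#' @export
fit_pairwise <- function(moments, learning_rate = 0.2, tol = 1e-6,
                         max_iter = 1e5) {
  stopifnot(inherits(moments, "mem_moments"))
  moments <- shrink_moments(moments)
  n <- length(moments$first)
  check_enumerable(n)
  target1 <- moments$first
  target2 <- moments$second
  S <- state_patterns(n)
  h <- numeric(n)
  J <- matrix(0, n, n)
  gap <- Inf
  for (iter in seq_len(max_iter)) {
    e <- -as.vector(S %*% h) - 0.5 * rowSums((S %*% J) * S)
    w <- exp(-(e - min(e)))
    p <- w / sum(w)
    m1 <- as.vector(crossprod(S, p))
    m2 <- crossprod(S, S * p)
    g1 <- target1 - m1
    g2 <- target2 - m2
    diag(g2) <- 0
    gap <- max(abs(g1), abs(g2))
    if (gap <= tol) {
      out <- mem_params(h, J, order = "pairwise")
      attr(out, "iterations") <- iter
      attr(out, "final_gap") <- gap
      attr(out, "converged") <- TRUE
      return(out)
    }
    h <- h + learning_rate * g1
    J <- J + learning_rate * g2
  }
  rlang::abort(
    sprintf(
      "Pairwise fit did not converge in %d steps (final moment gap %.3g > tol %.3g).",
      as.integer(max_iter), gap, tol
    ),
    class = "elscape_fit_nonconvergence",
    final_gap = gap
  )
}

#' Fit the independent (1st-order) maximum-entropy model
#'
#' With no couplings the model factorizes over nodes, so each field has the
#' closed form `h_i = atanh(<sigma_i>)`; `J` is identically zero.
#'
#' @inheritParams fit_pairwise
#' @return A [mem_params] of order `"independent"`.
#' @examples
#' fit_independent(empirical_moments(rbind(c(1, -1), c(-1, 1))))$h  # c(0, 0)
#' @export
fit_independent <- function(moments) {
  stopifnot(inherits(moments, "mem_moments"))
  moments <- shrink_moments(moments)
  mem_params(h = atanh(moments$first), order = "independent")
}

#' Fit accuracy r_D of the pairwise model
#'
#' Measures how much of the independent model's misfit the pairwise model
#' removes: `D_k` is the Kullback-Leibler divergence (nats) of the empirical
#' pattern distribution from model `k`, summed over observed patterns only
#' (unobserved patterns contribute zero by the `0 log 0 = 0` convention),
#' and `r_D = (D_1 - D_2) / D_1`. Values near 1 mean the pairwise model
#' captures essentially all structure the independent model misses.
#'
#' @param series The T x N +1/-1 series both models were fitted on.
#' @param pairwise,independent Fitted [mem_params] of the matching orders.
#' @return An object of class `mem_fit_accuracy`: list with `d1`, `d2`,
#'   `r_d` and `undefined` (`TRUE` when `D_1 = 0`, in which case `r_d` is
#'   `NA`).
#' @export
fit_accuracy <- function(series, pairwise, independent) {
  stopifnot(
    inherits(pairwise, "mem_params"), pairwise$order == "pairwise",
    inherits(independent, "mem_params"), independent$order == "independent"
  )
  X <- as_pm1_matrix(series, "series")
  n <- ncol(X)
  if (n != pairwise$n_nodes || n != independent$n_nodes) {
    rlang::abort("Series and model dimensions disagree.")
  }
  idx <- state_index(X) + 1L
  counts <- tabulate(idx, nbins = 2^n)
  obs <- which(counts > 0L)
  p_emp <- counts[obs] / nrow(X)
  p2 <- exact_distribution(pairwise)$prob[obs]
  p1 <- exact_distribution(independent)$prob[obs]
  d1 <- sum(p_emp * log(p_emp / p1))
  d2 <- sum(p_emp * log(p_emp / p2))
  undefined <- d1 <= 0
  if (undefined) {
    rlang::inform("D1 = 0: the independent model already fits perfectly; r_D undefined.")
  }
  structure(
    list(
      d1 = d1, d2 = d2,
      r_d = if (undefined) NA_real_ else (d1 - d2) / d1,
      undefined = undefined
    ),
    class = "mem_fit_accuracy"
  )
}

#' @export
print.mem_fit_accuracy <- function(x, ...) {
  cat(sprintf(
    "<mem_fit_accuracy> D1 = %.4g, D2 = %.4g nats, r_D = %s\n",
    x$d1, x$d2, if (x$undefined) "undefined" else sprintf("%.4f", x$r_d)
  ))
  invisible(x)
}

#' @rdname fit_accuracy
#' @param x A `mem_fit_accuracy` object.
#' @param ... Unused.
#' @export
glance.mem_fit_accuracy <- function(x, ...) {
  tibble::tibble(d1 = x$d1, d2 = x$d2, r_d = x$r_d, undefined = x$undefined)
}
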