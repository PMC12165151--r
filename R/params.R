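#' Maximum-entropy model parameters
#'
#' Container for the parameters of an independent (1st-order) or pairwise
#' (2nd-order) maximum-entropy model over `N` binary (+1/-1) nodes: the basal
#' activities `h` (length-`N` vector) and the symmetric pairwise couplings `J`
#' (`N x N` matrix with zero diagonal). Under the pairwise model the energy of
#' an activity pattern `V = (sigma_1, ..., sigma_N)` is
#' `E(V) = -sum_i h_i sigma_i - (1/2) sum_ij J_ij sigma_i sigma_j`
#' and pattern probabilities follow the Boltzmann distribution
#' `P(V) propto exp(-E(V))`.
#'
#' @param h Numeric vector of basal activities (dimensionless).
#' @param J Symmetric numeric matrix of pairwise couplings with zero
#'   diagonal; `NULL` (the default) means no couplings.
#' @param order `"pairwise"` or `"independent"`; the independent model must
#'   have all-zero `J`.
#'
#' @return An object of class `mem_params`: a list with elements `h`, `J`,
#'   `order` and `n_nodes`.
#' @examples
#' p <- mem_params(h = c(1, -1), J = matrix(c(0, 0.5, 0.5, 0), 2))
#' state_energy(c(1, 1), p)
#' @export
mem_params <- function(h, J = NULL, order = c("pairwise", "independent")) {
  order <- rlang::arg_match(order)
  h <- as.numeric(h)
  n <- length(h)
  if (n < 1L || anyNA(h)) {
    rlang::abort("`h` must be a non-empty numeric vector without NA.")
  }
  if (is.null(J)) J <- matrix(0, n, n)
  J <- unname(as.matrix(J))
  if (!is.numeric(J) || !identical(dim(J), c(n, n)) || anyNA(J)) {
    rlang::abort(sprintf("`J` must be a %d x %d numeric matrix without NA.", n, n))
  }
  if (max(abs(J - t(J))) > 1e-8) {
    rlang::abort("`J` must be symmetric.")
  }
  if (max(abs(diag(J))) > 1e-12) {
    rlang::abort("`J` must have a zero diagonal.")
  }
  if (order == "independent" && any(J != 0)) {
    rlang::abort("An independent-order model must have J identically zero.")
  }
  structure(
    list(h = h, J = (J + t(J)) / 2, order = order, n_nodes = n),
    class = "mem_params"
  )
}

#' @export
print.mem_params <- function(x, ...) {
  cat(sprintf(
    "<mem_params> %s model, N = %d nodes\n", x$order, x$n_nodes
  ))
  cat("  h:", paste(signif(x$h, 3), collapse = " "), "\n")
  if (x$order == "pairwise") {
    off <- x$J[upper.tri(x$J)]
    cat(sprintf(
      "  J: %d couplings in [%.3g, %.3g]\n",
      length(off), min(off), max(off)
    ))
  }
  it <- attr(x, "iterations")
  if (!is.null(it)) {
    cat(sprintf(
      "  fitted: %d gradient steps, final moment gap %.3g\n",
      it, attr(x, "final_gap")
    ))
  }
  invisible(x)
}

#' Tidy maximum-entropy parameters into a long tibble
#'
#' @param x A [mem_params] object.
#' @param ... Unused.
#' @return A tibble with columns `term` (`"h[i]"` or `"J[i,j]"`, upper
#'   triangle only), `node_i`, `node_j` (`NA` for fields) and `estimate`.
#' @export
tidy.mem_params <- function(x, ...) {
  n <- x$n_nodes
  ij <- which(upper.tri(x$J), arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(
      term = sprintf("h[%d]", seq_len(n)),
      node_i = seq_len(n), node_j = NA_integer_, estimate = x$h
    ),
    tibble::tibble(
      term = sprintf("J[%d,%d]", ij[, 1], ij[, 2]),
      node_i = as.integer(ij[, 1]), node_j = as.integer(ij[, 2]),
      estimate = x$J[ij]
    )
  )
}

#' One-row summary of a (fitted) parameter set
#'
#' @param x A [mem_params] object.
#' @param ... Unused.
#' @return A one-row tibble with `n_nodes`, `order`, and, when the object
#'   came out of [fit_pairwise()], `iterations`, `final_gap` and `converged`.
#' @export
glance.mem_params <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes,
    order = x$order,
    iterations = attr(x, "iterations") %||% NA_integer_,
    final_gap = attr(x, "final_gap") %||% NA_real_,
    converged = attr(x, "converged") %||% NA
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
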