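#' Gini coefficient of a nonnegative vector
#'
#' The mean-absolute-difference form
#' `G = sum_ij |x_i - x_j| / (2 n^2 mu)`, a scale-free index of inequality
#' or polarization: 0 for a perfectly even vector, `(n - 1)/n` for full
#' concentration in one entry. A length-1 or all-zero vector has no
#' polarization to measure; it returns 0 with attribute `undefined = TRUE`.
#'
#' @param values Nonnegative numeric vector, length >= 1.
#' @return A number in `[0, (n-1)/n]`, with logical attribute `undefined`.
#' @examples
#' gini(c(5, 5, 5, 5))  # 0
#' gini(c(0, 0, 0, 1))  # 0.75
#' gini(c(1, 2, 3, 4))  # 0.25
#' @export
gini <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 1L || anyNA(x)) {
    rlang::abort("`values` must be a non-empty numeric vector without NA.")
  }
  if (any(x < 0)) rlang::abort("`values` must be nonnegative.")
  n <- length(x)
  mu <- mean(x)
  if (n == 1L || mu == 0) {
    return(structure(0, undefined = TRUE))
  }
  xs <- sort(x)
  g <- 2 * sum(seq_len(n) * xs) / (n^2 * mu) - (n + 1) / n
  structure(max(0, g), undefined = FALSE)
}
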