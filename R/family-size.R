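#' Poisson family-size distribution
#'
#' Probability mass of the number of children per couple, `N ~ Poisson(lambda)`,
#' truncated at an order chosen so the neglected tail mass is below `tail_tol`.
#'
#' @param lambda Mean number of children per couple (>= 0).
#' @param n_max Truncation order. If `NULL` (default) the smallest order with
#'   `P(N > n_max) < tail_tol` is used.
#' @param tail_tol Permitted tail mass beyond `n_max` when `n_max` is chosen
#'   automatically; also used to check a user-supplied `n_max`.
#' @return A data.frame with columns `size` (0..n_max) and `prob`.
#' @examples
#' family_size_pmf(1.7)[1, ]  # P(N = 0) = exp(-1.7)
#' @export
family_size_pmf <- function(lambda, n_max = NULL, tail_tol = 1e-12) {
  check_lambda(lambda)
  if (length(lambda) != 1L) stop("`lambda` must be scalar", call. = FALSE)
  if (is.null(n_max)) {
    # qpois overshoots a little at extreme quantiles; that only adds rows
    n_max <- if (lambda == 0) 0L else
      as.integer(stats::qpois(tail_tol, lambda, lower.tail = FALSE)) + 1L
  } else {
    tail <- stats::ppois(n_max, lambda, lower.tail = FALSE)
    if (tail >= tail_tol)
      warning(sprintf("tail mass beyond n_max is %.3g (>= %.1g)", tail, tail_tol))
  }
  size <- 0:n_max
  data.frame(size = size, prob = stats::dpois(size, lambda))
}
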