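#' Intervention model specification
#'
#' Which behavioural rule sonless couples follow, and the threshold birth
#' order `n` at which they act.
#'
#' * `"universal"`: every family with `n` or more children whose first
#'   `n - 1` births were all girls intervenes at birth `n` (single shared
#'   threshold).
#' * `"stopping"`: the male-preferring stopping rule. Couples intervene only
#'   at their *last* birth, if still sonless then, and only if their family
#'   size is at least `n` (minimum threshold). A family of `N >= n` children
#'   intervenes iff its first `N - 1` births were all girls.
#'
#' @param variant `"universal"` or `"stopping"` (alias `"stopping_rule"`).
#' @param n Intervention threshold, integer >= 1.
#' @return An object of class `model_spec` with elements `variant` and `n`.
#' @examples
#' model_spec("stopping", n = 2)
#' @export
model_spec <- function(variant = c("stopping", "universal"), n = 2) {
  if (length(variant) == 1L && identical(variant, "stopping_rule"))
    variant <- "stopping"
  variant <- match.arg(variant)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  structure(list(variant = variant, n = as.integer(n)), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  lab <- c(universal = "universal threshold", stopping = "stopping rule")[x$variant]
  cat(sprintf("Intervention model: %s, n = %d (APFB %.0f%%)\n", lab, x$n, apfb(x$n)))
  invisible(x)
}

check_lambda <- function(lam, allow_zero = TRUE) {
  if (!is.numeric(lam) || any(!is.finite(lam)))
    stop("`lambda` must be finite numeric", call. = FALSE)
  if (any(lam < 0) || (!allow_zero && any(lam == 0)))
    stop(sprintf("`lambda` must be %s", if (allow_zero) ">= 0" else "> 0"),
         call. = FALSE)
  invisible(lam)
}
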