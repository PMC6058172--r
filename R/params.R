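#' Natural birth parameters
#'
#' Bundle of the natural (intervention-free) female-birth propensity `p`.
#' The default `p = 0.486` matches the commonly cited natural sex ratio at
#' birth of about 946 girls per 1000 boys (105.8 boys per 100 girls), i.e.
#' `p/(1-p)` close to 0.946.
#'
#' @param p Probability that a birth is female absent any intervention.
#'   Must lie strictly in (0, 1).
#' @return An object of class `natural_params` with element `p`.
#' @examples
#' natural_params()          # default p = 0.486
#' natural_params(p = 0.5)   # symmetric benchmark
#' @export
natural_params <- function(p = 0.486) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("`p` must be a single number strictly between 0 and 1", call. = FALSE)
  structure(list(p = p), class = "natural_params")
}

#' @export
print.natural_params <- function(x, ...) {
  cat(sprintf("Natural birth parameters: p (female) = %g\n", x$p))
  b <- natural_srb(x)
  cat(sprintf("  benchmark SRB: %.2f boys per 100 girls (%.0f girls per 1000 boys)\n",
              b$boys_per_100_girls, b$girls_per_1000_boys))
  invisible(x)
}

# Coerce p (numeric) or natural_params to natural_params
as_natural_params <- function(params) {
  if (inherits(params, "natural_params")) return(params)
  natural_params(p = params)
}

#' Natural benchmark sex ratios at birth
#'
#' The SRB a population exhibits when no couple intervenes, in the two
#' conventions in common use.
#'
#' @param params A [natural_params()] object, or a bare numeric `p`.
#' @return A list with `boys_per_100_girls` = `100*(1-p)/p` and
#'   `girls_per_1000_boys` = `1000*p/(1-p)`. The two are mutually consistent:
#'   their product is 1e5 by construction.
#' @examples
#' natural_srb(natural_params(0.486))  # ~105.76 boys per 100 girls
#' @export
natural_srb <- function(params = natural_params()) {
  params <- as_natural_params(params)
  p <- params$p
  list(boys_per_100_girls = 100 * (1 - p) / p,
       girls_per_1000_boys = 1000 * p / (1 - p))
}

#' Acceptable proportion of female births (APFB)
#'
#' Guilmoto's reparameterisation of the intervention threshold `n`: the
#' percentage of female births a couple tolerates before sex-selecting,
#' `APFB = 100 - 100/n`. A threshold of 1 tolerates no daughters (APFB 0%);
#' n = 2 tolerates one daughter in two children (50%), and so on.
#'
#' @param n Intervention threshold, integer birth order >= 1. Vectorised.
#' @return APFB in percent.
#' @examples
#' apfb(c(1, 2, 4))  # 0, 50, 75
#' @export
apfb <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1) || any(n != floor(n)))
    stop("`n` must be integer birth order(s) >= 1", call. = FALSE)
  100 - 100 / n
}
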