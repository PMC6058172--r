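#' Forward model: expected births, SRB and intervening fractions
#'
#' Closed-form expectations per couple for a population with Poisson(`lambda`)
#' family sizes, natural female-birth probability `p`, and sonless couples
#' sex-selecting according to `spec`. Intervention converts the sex of one
#' designated birth (in vitro fertilisation-like: the designated birth is male
#' with certainty); it never changes family size, so expected total births per
#' couple always equal `lambda`.
#'
#' Under the universal threshold, a family of `N >= n` children intervenes at
#' birth `n` iff its first `n - 1` births were all girls (probability
#' `p^(n-1)`); the expected excess of boys per couple is `p^n * P(N >= n)`.
#' Under the stopping rule, a family of `N >= n` children intervenes at its
#' last birth iff its first `N - 1` births were all girls (probability
#' `p^(N-1)`); the expected excess of boys per couple is the partial
#' exponential sum
#' `S = sum_{N >= n} Pois(N; lambda) p^N = exp(lambda (p - 1)) * P(M >= n)`
#' with `M ~ Poisson(lambda p)`, evaluated through the stable upper Poisson
#' tail rather than naive subtraction.
#'
#' Phi is the proportion of *all* couples intervening (childless couples in
#' the denominator); Psi rescales to parents only, `Psi = Phi / (1 - e^-lambda)`.
#'
#' @param lambda Mean children per couple (>= 0). Vectorised.
#' @param spec A [model_spec()]; or use the `predict_universal()` /
#'   `predict_stopping()` shorthands with a bare threshold `n`.
#' @param n Intervention threshold (shorthand forms).
#' @param params A [natural_params()] object or bare numeric `p`.
#' @return A data.frame of class `model_prediction`, one row per `lambda`,
#'   with columns:
#'   \describe{
#'     \item{lambda}{input mean family size}
#'     \item{e_boys, e_girls}{expected boys / girls per couple}
#'     \item{r_prop}{proportion of births male (canonical SRB representation)}
#'     \item{r_b100g}{SRB as boys per 100 girls}
#'     \item{phi}{proportion of all couples intervening}
#'     \item{psi}{proportion of parents (couples with >= 1 child) intervening}
#'     \item{degenerate}{TRUE where `e_girls <= 0` would make the SRB
#'       undefined; `r_b100g` is then `Inf` (or `NaN` at `lambda = 0`)}
#'   }
#' @examples
#' predict_stopping(lambda = 1.196, n = 2)   # near the peak SRB distortion
#' predict_universal(lambda = 1.7, n = 4)
#' @export
predict_family_model <- function(lambda, spec = model_spec(),
                                 params = natural_params()) {
  check_lambda(lambda)
  stopifnot(inherits(spec, "model_spec"))
  params <- as_natural_params(params)
  p <- params$p
  n <- spec$n

  extra_boys <- switch(spec$variant,
    universal = p^n * stats::ppois(n - 1, lambda, lower.tail = FALSE),
    stopping  = stopping_excess_boys(lambda, n, p))
  phi <- extra_boys / p

  e_boys  <- lambda * (1 - p) + extra_boys
  e_girls <- lambda * p - extra_boys
  degenerate <- e_girls <= 0 & lambda > 0
  r_prop  <- ifelse(lambda > 0, e_boys / lambda, NA_real_)
  r_b100g <- ifelse(lambda == 0, NA_real_,
             ifelse(degenerate, Inf, 100 * e_boys / e_girls))
  psi <- ifelse(lambda > 0, phi / -expm1(-lambda), NA_real_)

  structure(
    data.frame(lambda = lambda, e_boys = e_boys, e_girls = e_girls,
               r_prop = r_prop, r_b100g = r_b100g,
               phi = phi, psi = psi, degenerate = degenerate),
    class = c("model_prediction", "data.frame"),
    variant = spec$variant, n = n, p = p)
}

# S = sum_{N>=n} dpois(N, lambda) * p^N, via the Poisson(lambda*p) upper tail
stopping_excess_boys <- function(lambda, n, p) {
  exp(lambda * (p - 1)) * stats::ppois(n - 1, lambda * p, lower.tail = FALSE)
}

#' @rdname predict_family_model
#' @export
predict_universal <- function(lambda, n = 2, params = natural_params()) {
  predict_family_model(lambda, model_spec("universal", n), params)
}

#' @rdname predict_family_model
#' @export
predict_stopping <- function(lambda, n = 2, params = natural_params()) {
  predict_family_model(lambda, model_spec("stopping", n), params)
}

#' @export
print.model_prediction <- function(x, ...) {
  cat(sprintf("Model prediction (%s, n = %d, p = %g)\n",
              attr(x, "variant"), attr(x, "n"), attr(x, "p")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Intervening parents from intervening couples
#'
#' Converts Phi, the proportion of all couples intervening, to Psi, the
#' proportion among parents (couples with at least one child):
#' `Psi = Phi / (1 - exp(-lambda))`.
#'
#' @param phi Intervening-couple fraction, `0 <= phi <= 1 - exp(-lambda)`.
#' @param lambda Mean children per couple, strictly positive.
#' @return Psi, the intervening-parent fraction.
#' @examples
#' psi_from_phi(0.1951, lambda = 2.5)  # ~0.2125
#' @export
psi_from_phi <- function(phi, lambda) {
  check_lambda(lambda, allow_zero = FALSE)
  parent_frac <- -expm1(-lambda)
  if (any(phi < 0) || any(phi > parent_frac + 1e-12))
    stop("`phi` must lie in [0, 1 - exp(-lambda)]", call. = FALSE)
  phi / parent_frac
}

#' Expected abortions under the sex-selective-abortion variant
#'
#' If intervention is implemented by fetal sex diagnosis followed by abortion
#' of female fetuses (rather than a preconception method), an intervening
#' couple aborts and re-conceives until a male fetus occurs. The number of
#' abortions per intervening couple is geometric with mean `p / (1 - p)`, so
#' the expected total per couple in the population is `phi * p / (1 - p)`.
#' At `p = 0.486` this is 0.946 abortions per intervening couple — close to,
#' though slightly below, the single intervention a preconception method
#' requires, which is why the two mechanisms imply a similar number of
#' interventions. The expected sex composition of births is identical under
#' the two mechanisms.
#'
#' @param phi Intervening-couple fraction in `[0, 1]`. Vectorised.
#' @param params A [natural_params()] object or bare numeric `p`.
#' @return Expected abortions per couple, `phi * p / (1 - p)`.
#' @examples
#' expected_abortion_interventions(0.10)  # ~0.0946 at p = 0.486
#' @export
expected_abortion_interventions <- function(phi, params = natural_params()) {
  params <- as_natural_params(params)
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("`phi` must lie in [0, 1]", call. = FALSE)
  phi * params$p / (1 - params$p)
}
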