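#' Sex-selection propensity from an observed (SRB, fertility) pair
#'
#' Inverts the forward model's birth accounting. With `r = srb/100` (boys per
#' girl) and mean family size `lambda` (total fertility rate in practice),
#' the expected composition `e_boys = lambda (1-p) + p Phi`,
#' `e_girls = lambda p - p Phi` — each intervening couple forces one birth
#' male, converting a would-be girl with probability `p` — solves to
#' \deqn{\Phi = \lambda \, (p r - (1 - p)) / (p (1 + r)).}
#' This closed form is exactly consistent with [predict_stopping()] for every
#' `(lambda, n)`: feeding a forward prediction's `(r_b100g, lambda)` back in
#' recovers its `phi` to machine precision. It treats Phi as an effective
#' population propensity and needs no assumption about the threshold `n`.
#'
#' An observed SRB at or below the natural benchmark `100 (1-p)/p` yields a
#' reported `phi` of 0 with `below_benchmark = TRUE`; the signed raw solution
#' is kept in `phi_raw` for diagnostics. An implied `phi > 1` is flagged
#' `implausible`.
#'
#' @param srb Observed SRB in boys per 100 girls (> 0). Vectorised.
#' @param tfr Observed total fertility rate, used as `lambda` (> 0).
#' @param params A [natural_params()] object or bare numeric `p`.
#' @return A data.frame of class `propensity_estimate` with columns `tfr`,
#'   `srb`, `phi`, `phi_raw`, `psi`, `excess_boys_per_couple` (`p * phi`),
#'   `below_benchmark`, `implausible`.
#' @examples
#' phi_from_observation(srb = 130.6, tfr = 1.196)   # ~0.129
#' @export
phi_from_observation <- function(srb, tfr, params = natural_params()) {
  params <- as_natural_params(params)
  p <- params$p
  if (any(!is.finite(srb)) || any(srb <= 0))
    stop("`srb` must be positive (boys per 100 girls)", call. = FALSE)
  if (any(!is.finite(tfr)) || any(tfr <= 0))
    stop("`tfr` must be positive", call. = FALSE)
  if (length(srb) != length(tfr)) {
    k <- max(length(srb), length(tfr))
    srb <- rep_len(srb, k); tfr <- rep_len(tfr, k)
  }
  r <- srb / 100
  phi_raw <- tfr * (p * r - (1 - p)) / (p * (1 + r))
  below <- phi_raw <= 0
  phi <- pmax(phi_raw, 0)
  structure(
    data.frame(tfr = tfr, srb = srb, phi = phi, phi_raw = phi_raw,
               psi = phi / -expm1(-tfr),
               excess_boys_per_couple = p * phi,
               below_benchmark = below,
               implausible = phi > 1),
    class = c("propensity_estimate", "data.frame"), p = p)
}

#' SRB implied by a fixed intervening fraction
#'
#' The forward relation at constant propensity: the exact inverse of
#' [phi_from_observation()],
#' `srb = 100 (lambda (1-p) + p phi) / (lambda p - p phi)`.
#' At any fixed `phi > 0` the SRB rises steeply as `lambda` falls — the
#' disproportionality effect: the same number of sex-converted births weighs
#' more in a smaller birth cohort, so SRB trends overstate behavioural change
#' wherever fertility is declining.
#'
#' @param phi Intervening-couple fraction (>= 0). Vectorised with `lambda`.
#' @param lambda Mean children per couple (> 0).
#' @param params A [natural_params()] object or bare numeric `p`.
#' @return SRB in boys per 100 girls; `Inf` (with a degenerate warning) where
#'   `lambda p - p phi <= 0`.
#' @examples
#' srb_at_fixed_phi(0.20, lambda = 1.0)  # ~157.2
#' srb_at_fixed_phi(0, lambda = 3)       # natural benchmark
#' @export
srb_at_fixed_phi <- function(phi, lambda, params = natural_params()) {
  params <- as_natural_params(params)
  p <- params$p
  check_lambda(lambda, allow_zero = FALSE)
  if (any(!is.finite(phi)) || any(phi < 0))
    stop("`phi` must be >= 0", call. = FALSE)
  num <- lambda * (1 - p) + p * phi
  den <- lambda * p - p * phi
  if (any(den <= 0)) {
    warning("degenerate: phi implies no girls at this lambda (SRB = Inf)",
            call. = FALSE)
  }
  ifelse(den > 0, 100 * num / den, Inf)
}

#' Batch propensity estimation over an observation table
#'
#' Applies [phi_from_observation()] to every row of an observation table and
#' overlays the cross-record ordinary-least-squares line of Phi on SRB. The
#' fitted line is the expected propensity given a record's SRB under the
#' average relationship across records; positive residuals mark regions whose
#' propensity exceeds what their SRB alone would suggest (typically the
#' higher-fertility regions, by the disproportionality effect).
#'
#' @param obs An `observation_table` (see [read_observations()]) or a
#'   data.frame with columns `label`, `period`, `tfr`, `srb`
#'   (`srb` in boys per 100 girls).
#' @param params A [natural_params()] object or bare numeric `p`. When `obs`
#'   is an `observation_table` carrying its own benchmark `p`, that value is
#'   used unless `params` is supplied explicitly.
#' @return A data.frame of class `propensity_table`: the input columns plus
#'   `phi`, `psi`, `excess_boys_per_couple`, `below_benchmark`, `implausible`,
#'   `phi_fit` (OLS expectation of Phi given SRB) and `residual`
#'   (`phi - phi_fit`). Implausible rows are flagged and excluded from the
#'   fit but retained in the output. The fit coefficients are stored in
#'   `attr(, "fit")` as `c(intercept, slope)`.
#' @examples
#' obs <- data.frame(label = c("A", "B"), period = "2005",
#'                   tfr = c(2, 4), srb = c(112, 112))
#' batch_estimate(obs)  # equal SRB: the higher-fertility region has larger phi
#' @export
batch_estimate <- function(obs, params = NULL) {
  if (is.null(params)) {
    params <- attr(obs, "p")
    if (is.null(params)) params <- natural_params()
  }
  params <- as_natural_params(params)
  obs <- as.data.frame(obs)
  if (nrow(obs) == 0L) stop("empty observation series", call. = FALSE)
  need <- c("label", "period", "tfr", "srb")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  est <- phi_from_observation(obs$srb, obs$tfr, params)
  out <- cbind(obs[need], est[c("phi", "psi", "excess_boys_per_couple",
                                "below_benchmark", "implausible")])

  usable <- !out$implausible & is.finite(out$phi) & is.finite(out$srb)
  if (sum(usable) >= 2L && stats::var(out$srb[usable]) > 0) {
    fit <- stats::lm(phi ~ srb, data = out[usable, ])
    coefs <- stats::coef(fit)
    out$phi_fit <- coefs[1L] + coefs[2L] * out$srb
  } else {
    # one record (or no SRB spread): the mean relationship is the record itself
    coefs <- c(`(Intercept)` = mean(out$phi[usable]), srb = 0)
    out$phi_fit <- ifelse(usable, out$phi, NA_real_)
  }
  out$residual <- out$phi - out$phi_fit
  out$phi_fit[!usable] <- NA_real_
  out$residual[!usable] <- NA_real_
  structure(out, class = c("propensity_table", "data.frame"),
            p = params$p, fit = coefs)
}
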