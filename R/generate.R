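#' Synthetic observation tables with known ground truth
#'
#' Emits a table shaped like the national/state (TFR, SRB) series the
#' estimator consumes — one row per region or period — with the true
#' sex-selection propensity recorded alongside, for recovery tests. Each
#' scenario row gives a mean family size `lambda` and *either* a propensity
#' `phi` *or* a stopping-rule threshold `n` (exactly one of the two).
#'
#' In `"deterministic"` mode SRB values come from the closed forms
#' ([srb_at_fixed_phi()] or [predict_stopping()]) and `tfr = lambda`; batch
#' estimation recovers `phi_true` to machine precision. In `"noisy"` mode
#' each row is a finite simulated cohort: `n`-mode rows run the stopping-rule
#' microsimulation; `phi`-mode rows select intervening couples among parents
#' with probability `phi / (1 - exp(-lambda))` (so the expected all-couple
#' intervening fraction is `phi`) and force their last birth male. Noisy rows
#' record the *realised* cohort TFR and SRB, plus `se_phi`, the delta-method
#' standard error of the propensity estimate from that row
#' (`sd(u_i)/sqrt(m)` with `u_i = (p b_i - (1-p) g_i)/p` over couples).
#'
#' @param scenarios data.frame with columns `label`, `lambda`, and `phi`
#'   and/or `n` (use `NA` for the unused one per row); optional `period`.
#' @param params A [natural_params()] object or bare numeric `p`.
#' @param seed Integer RNG seed (noisy mode).
#' @param mode `"deterministic"` or `"noisy"`.
#' @param cohort_size Couples per row in noisy mode.
#' @return An `observation_table` data.frame (columns `label`, `period`,
#'   `tfr`, `srb`, `phi_true`, and `se_phi` in noisy mode) with attributes
#'   `srb_unit = "b100g"`, `p`, and `source`.
#' @examples
#' sc <- data.frame(label = c("low", "high"), lambda = c(2, 4),
#'                  phi = c(0.05, 0.05), n = NA)
#' generate_observation_table(sc, seed = 1)
#' @export
generate_observation_table <- function(scenarios, params = natural_params(),
                                       seed = NULL,
                                       mode = c("deterministic", "noisy"),
                                       cohort_size = 1e5) {
  mode <- match.arg(mode)
  params <- as_natural_params(params)
  p <- params$p
  sc <- as.data.frame(scenarios)
  if (nrow(sc) == 0L) stop("empty scenario list", call. = FALSE)
  if (!"label" %in% names(sc) || !"lambda" %in% names(sc))
    stop("scenarios need `label` and `lambda` columns", call. = FALSE)
  if (!"phi" %in% names(sc)) sc$phi <- NA_real_
  if (!"n" %in% names(sc)) sc$n <- NA_integer_
  if (!"period" %in% names(sc)) sc$period <- "synthetic"
  has_phi <- !is.na(sc$phi); has_n <- !is.na(sc$n)
  if (any(has_phi & has_n))
    stop("scenario row(s) ", paste(which(has_phi & has_n), collapse = ", "),
         ": give `phi` or `n`, not both", call. = FALSE)
  if (any(!has_phi & !has_n))
    stop("scenario row(s) ", paste(which(!has_phi & !has_n), collapse = ", "),
         ": give one of `phi` or `n`", call. = FALSE)
  check_lambda(sc$lambda, allow_zero = FALSE)

  if (mode == "noisy") {
    if (is.null(seed)) stop("`seed` is required in noisy mode", call. = FALSE)
    set.seed(seed)
  }

  rows <- lapply(seq_len(nrow(sc)), function(i) {
    lam <- sc$lambda[i]
    if (mode == "deterministic") {
      if (has_phi[i]) {
        phi_true <- sc$phi[i]
        srb <- srb_at_fixed_phi(phi_true, lam, params)
      } else {
        pred <- predict_stopping(lam, sc$n[i], params)
        phi_true <- pred$phi
        srb <- pred$r_b100g
      }
      data.frame(label = sc$label[i], period = sc$period[i],
                 tfr = lam, srb = srb, phi_true = phi_true)
    } else {
      noisy_row(sc$label[i], sc$period[i], lam,
                phi = if (has_phi[i]) sc$phi[i] else NULL,
                n = if (has_n[i]) sc$n[i] else NULL,
                p = p, m = as.integer(cohort_size))
    }
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("observation_table", "data.frame"),
            srb_unit = "b100g", p = p,
            source = sprintf("synthetic (%s mode)", mode))
}

# One simulated cohort row; per-row RNG continues the stream set by the caller
noisy_row <- function(label, period, lam, phi = NULL, n = NULL, p, m) {
  if (!is.null(n)) {
    phi_true <- predict_stopping(lam, n, natural_params(p))$phi
    N <- stats::rpois(m, lam)
    B <- sum(N)
    boy <- stats::rbinom(B, 1L, 1 - p)
    off <- cumsum(N) - N
    cb <- c(0L, cumsum(boy))
    eligible <- which(N >= n)
    prior_end <- off[eligible] + N[eligible] - 1L
    hit <- (cb[prior_end + 1L] - cb[off[eligible] + 1L]) == 0L
    forced <- prior_end[hit] + 1L
    boy[forced] <- 1L
  } else {
    phi_true <- phi
    psi <- phi / -expm1(-lam)
    if (psi > 1)
      stop(sprintf("row '%s': phi = %g exceeds the parent fraction %g",
                   label, phi, -expm1(-lam)), call. = FALSE)
    N <- stats::rpois(m, lam)
    B <- sum(N)
    boy <- stats::rbinom(B, 1L, 1 - p)
    parents <- which(N >= 1L)
    pick <- parents[stats::runif(length(parents)) < psi]
    off <- cumsum(N) - N
    boy[off[pick] + N[pick]] <- 1L   # force last birth male
  }
  cb <- c(0L, cumsum(boy))
  off <- cumsum(N) - N
  b_i <- cb[off + N + 1L] - cb[off + 1L]
  g_i <- N - b_i
  tb <- sum(b_i); tg <- sum(g_i)
  u <- (p * b_i - (1 - p) * g_i) / p
  data.frame(label = label, period = period,
             tfr = (tb + tg) / m, srb = 100 * tb / tg,
             phi_true = phi_true,
             se_phi = stats::sd(u) / sqrt(m))
}
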