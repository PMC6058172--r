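#' Seeded Monte Carlo cohort of couples
#'
#' Micro-level implementation of the behavioural rules, used as the
#' independent check on every closed form. For each couple the family size is
#' drawn `N ~ Poisson(lambda)`; each birth is then a girl with probability
#' `p`. Under the universal threshold a family with `N >= n` whose first
#' `n - 1` births were all girls has birth `n` forced male; under the
#' stopping rule a family with `N >= n` whose first `N - 1` births were all
#' girls has its last birth forced male. Each couple intervenes at most once,
#' and the intervention flag is raised whenever the sonless condition is met
#' (the forced birth may or may not have been a boy by chance).
#'
#' Draw order is fixed and documented: all `N` first (one `rpois` call),
#' then all natural birth sexes couple by couple (one `rbinom` call), then —
#' in the abortion variant — the per-intervener abortion counts. Identical
#' inputs and seed give bit-identical results.
#'
#' Standard errors: `se_phi` is binomial,
#' `sqrt(phi_hat (1 - phi_hat) / n_couples)`; `se_srb` is the ratio-estimator
#' (delta-method) SE of `100 * boys/girls` over couples,
#' `100 * sqrt(sum((b_i - R g_i)^2)) / girls` with `R = boys/girls` and
#' `(b_i, g_i)` the per-couple counts.
#'
#' @param n_couples Number of couples (>= 1).
#' @param lambda Mean children per couple (>= 0).
#' @param spec A [model_spec()].
#' @param params A [natural_params()] object or bare numeric `p`.
#' @param seed Integer RNG seed; required for reproducibility.
#' @param keep_families If TRUE, also return a per-family data.frame
#'   (`n_children`, `n_boys`, `sexes` as a "GGB"-style string, `intervened`,
#'   `intervention_order`). Intended for small cohorts.
#' @return An object of class `cohort_result`: a list with `n_couples`,
#'   `lambda`, `variant`, `n`, `p`, `seed`, `total_births`, `total_boys`,
#'   `total_girls`, `n_interventions`, `srb_b100g`, `phi_hat`, `psi_hat`
#'   (interventions over couples with >= 1 child), `se_srb`, `se_phi`,
#'   `last_birth_srb` and `earlier_birth_srb` (boys per 100 girls at last vs
#'   earlier births among families with >= 2 children; the stopping-rule
#'   signature), and `families` when requested. `srb_b100g` is `NA` when no
#'   girls (or no births) occur.
#' @examples
#' sim <- simulate_cohort(1e4, lambda = 2.5, spec = model_spec("stopping", 2),
#'                        seed = 1)
#' sim$phi_hat  # close to predict_stopping(2.5, 2)$phi
#' @export
simulate_cohort <- function(n_couples, lambda, spec = model_spec(),
                            params = natural_params(), seed,
                            keep_families = FALSE) {
  core <- simulate_core(n_couples, lambda, spec, params, seed)
  build_cohort_result(core, spec, keep_families)
}

#' Cohort under the sex-selective-abortion mechanism
#'
#' Identical behavioural rules and identical birth outcomes (given the seed)
#' as [simulate_cohort()], but intervention is implemented by fetal sex
#' diagnosis and abortion of female fetuses at the designated birth: an
#' intervening couple re-conceives until a male fetus occurs, each aborted
#' female conception counted. Abortions per intervening couple are geometric
#' with mean `p / (1 - p)`; couples whose designated conception is male by
#' chance abort zero times.
#'
#' @inheritParams simulate_cohort
#' @return A `cohort_result` as for [simulate_cohort()], with additional
#'   elements `n_abortions` (total) and `mean_abortions_per_intervener`, and
#'   `se_abortions` (SE of the total, from the empirical per-intervener
#'   variance).
#' @examples
#' simulate_abortion_variant(1e4, 2.5, model_spec("stopping", 2),
#'                           seed = 1)$mean_abortions_per_intervener
#' @export
simulate_abortion_variant <- function(n_couples, lambda, spec = model_spec(),
                                      params = natural_params(), seed,
                                      keep_families = FALSE) {
  core <- simulate_core(n_couples, lambda, spec, params, seed)
  res <- build_cohort_result(core, spec, keep_families)
  m <- res$n_interventions
  # abortions = female conceptions before the first male at the forced slot
  ab <- if (m > 0) stats::rgeom(m, prob = 1 - core$p) else integer(0)
  res$n_abortions <- sum(ab)
  res$mean_abortions_per_intervener <- if (m > 0) mean(ab) else NA_real_
  res$se_abortions <- if (m > 1) sqrt(m * stats::var(ab)) else 0
  res
}

# Shared micro-simulation. Returns birth-level vectors and per-couple indices.
simulate_core <- function(n_couples, lambda, spec, params, seed) {
  if (!is.numeric(n_couples) || length(n_couples) != 1L || n_couples < 1)
    stop("`n_couples` must be >= 1", call. = FALSE)
  n_couples <- as.integer(n_couples)
  check_lambda(lambda)
  stopifnot(inherits(spec, "model_spec"))
  params <- as_natural_params(params)
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  p <- params$p
  n <- spec$n

  set.seed(seed)
  N <- stats::rpois(n_couples, lambda)
  B <- sum(N)
  boy <- if (B > 0) stats::rbinom(B, 1L, 1 - p) else integer(0)

  off <- cumsum(N) - N                     # 0-based start offset per couple
  cb <- c(0L, cumsum(boy))                 # prefix boy counts

  eligible <- which(N >= n)
  if (length(eligible)) {
    offe <- off[eligible]
    prior_end <- if (spec$variant == "universal") offe + n - 1L
                 else offe + N[eligible] - 1L
    boys_prior <- cb[prior_end + 1L] - cb[offe + 1L]
    hit <- boys_prior == 0L              # sonless at the designated birth
    intervened_idx <- eligible[hit]
    forced_slot <- prior_end[hit] + 1L
  } else {
    intervened_idx <- integer(0)
    forced_slot <- integer(0)
  }
  boy_forced <- boy
  boy_forced[forced_slot] <- 1L

  list(n_couples = n_couples, lambda = lambda, p = p, seed = seed,
       N = N, off = off, boy_natural = boy, boy = boy_forced,
       intervened_idx = intervened_idx, forced_slot = forced_slot)
}

build_cohort_result <- function(core, spec, keep_families) {
  N <- core$N; off <- core$off; boy <- core$boy
  m <- core$n_couples
  B <- sum(N)
  cb <- c(0L, cumsum(boy))
  boys_per_fam <- cb[off + N + 1L] - cb[off + 1L]
  girls_per_fam <- N - boys_per_fam

  total_boys <- sum(boys_per_fam)
  total_girls <- B - total_boys
  n_int <- length(core$intervened_idx)
  phi_hat <- n_int / m
  n_parents <- sum(N >= 1L)
  psi_hat <- if (n_parents > 0) n_int / n_parents else NA_real_

  if (total_girls > 0) {
    R <- total_boys / total_girls
    srb <- 100 * R
    se_srb <- 100 * sqrt(sum((boys_per_fam - R * girls_per_fam)^2)) / total_girls
  } else {
    srb <- NA_real_; se_srb <- NA_real_
  }
  se_phi <- sqrt(phi_hat * (1 - phi_hat) / m)

  # stopping-rule signature: sex ratio at last vs earlier births (N >= 2)
  multi <- which(N >= 2L)
  if (length(multi)) {
    last_idx <- off[multi] + N[multi]
    lb <- sum(boy[last_idx]); lg <- length(last_idx) - lb
    eb <- sum(boys_per_fam[multi]) - lb
    eg <- sum(girls_per_fam[multi]) - lg
    last_srb <- if (lg > 0) 100 * lb / lg else NA_real_
    earlier_srb <- if (eg > 0) 100 * eb / eg else NA_real_
  } else {
    last_srb <- earlier_srb <- NA_real_
  }

  res <- list(n_couples = m, lambda = core$lambda, variant = spec$variant,
              n = spec$n, p = core$p, seed = core$seed,
              total_births = B, total_boys = total_boys,
              total_girls = total_girls, n_interventions = n_int,
              srb_b100g = srb, phi_hat = phi_hat, psi_hat = psi_hat,
              se_srb = se_srb, se_phi = se_phi,
              last_birth_srb = last_srb, earlier_birth_srb = earlier_srb,
              boys_per_couple = NULL)

  if (keep_families) {
    sex_chr <- ifelse(boy == 1L, "B", "G")
    fam_id <- rep.int(seq_len(m), N)
    sexes <- character(m)
    sexes[N > 0] <- vapply(split(sex_chr, factor(fam_id, levels = seq_len(m)))[N > 0],
                           paste0, character(1), collapse = "")
    intervention_order <- rep(NA_integer_, m)
    intervention_order[core$intervened_idx] <-
      as.integer(core$forced_slot - off[core$intervened_idx])
    res$families <- data.frame(
      n_children = N, n_boys = boys_per_fam, sexes = sexes,
      intervened = seq_len(m) %in% core$intervened_idx,
      intervention_order = intervention_order)
  }
  structure(res, class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d couples, lambda = %g, %s n = %d, p = %g, seed = %s\n",
              x$n_couples, x$lambda, x$variant, x$n, x$p, format(x$seed)))
  cat(sprintf("  births %d (boys %d / girls %d), SRB = %s boys per 100 girls (SE %.3g)\n",
              x$total_births, x$total_boys, x$total_girls,
              formatC(x$srb_b100g, format = "f", digits = 2), x$se_srb))
  cat(sprintf("  interventions %d: phi_hat = %.4f (SE %.3g), psi_hat = %.4f\n",
              x$n_interventions, x$phi_hat, x$se_phi, x$psi_hat))
  if (!is.null(x$n_abortions))
    cat(sprintf("  abortions %d (%.3f per intervening couple)\n",
                x$n_abortions, x$mean_abortions_per_intervener))
  invisible(x)
}
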