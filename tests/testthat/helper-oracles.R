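# Independent oracles used across the suite.
#
# enumerate_model() applies the micro-level behavioural rules to every sex
# sequence of every family size (exhaustive enumeration under a truncated
# Poisson), sharing no algebra with the package's closed forms.

enumerate_model <- function(lambda, n, p, variant, n_max = 14L) {
  e_boys <- 0; e_girls <- 0; phi <- 0
  for (N in 0:n_max) {
    pN <- dpois(N, lambda)
    if (N == 0L || pN == 0) next
    # rows = all 2^N sequences; 1 = girl
    seqs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), N)))
    girls <- rowSums(seqs)
    prob <- pN * p^girls * (1 - p)^(N - girls)
    eligible <- N >= n
    if (eligible) {
      k <- if (variant == "universal") n else N  # designated birth order
      prior_all_girls <- if (k == 1L) rep(TRUE, nrow(seqs))
                         else rowSums(seqs[, seq_len(k - 1L), drop = FALSE]) == k - 1L
      intervene <- prior_all_girls
      girls_out <- girls - intervene * seqs[, k]  # forced slot becomes a boy
      phi <- phi + sum(prob * intervene)
    } else {
      girls_out <- girls
    }
    e_girls <- e_girls + sum(prob * girls_out)
    e_boys <- e_boys + sum(prob * (N - girls_out))
  }
  list(e_boys = e_boys, e_girls = e_girls, phi = phi,
       r_b100g = 100 * e_boys / e_girls)
}

# Brute-force partial Poisson summation for the stopping-rule excess boys
bf_stopping_excess <- function(lambda, n, p, n_max = 300L) {
  N <- n:n_max
  sum(dpois(N, lambda) * p^N)
}

# Grid-scan argmax oracle
grid_argmax <- function(f, lo, hi, step) {
  g <- seq(lo, hi, by = step)
  g[which.max(f(g))]
}
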