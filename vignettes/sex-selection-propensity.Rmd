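---
title: "Modelling the sex ratio at birth and prenatal sex-selection propensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the sex ratio at birth and prenatal sex-selection propensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srbsel)
```

## The problem

In populations with strong son preference and access to prenatal sex
determination, the sex ratio at birth (SRB) is masculinised and is routinely
read as a direct indicator of how widespread prenatal sex selection is.
`srbsel` implements a probabilistic model of family composition that shows
why that reading fails when fertility is changing, and provides the
alternative indicator it motivates: the *sex-selection propensity* $\Phi$,
the proportion of couples who intervene to secure a son.

## The model

Let $\lambda$ be the mean number of children per couple, with family sizes
$N \sim \mathrm{Poisson}(\lambda)$, and let $p$ be the natural probability
that a birth is a girl. The default $p = 0.486$ matches the widely used
natural benchmark of about 946 girls per 1000 boys ($p/(1-p) \approx
0.946$), i.e. about 105.8 boys per 100 girls; all functions accept any
$p \in (0,1)$, and applied propensity estimates shift slightly with the
benchmark adopted, so output tables always record the $p$ they used.

Sonless couples sex-select under one of two behavioural rules, both
parameterised by a threshold birth order $n \ge 1$ (equivalently Guilmoto's
acceptable proportion of female births, $\mathrm{APFB} = 100 - 100/n$):

* **Universal threshold** (`predict_universal()`): a family with $N \ge n$
  children whose first $n-1$ births were all girls (probability $p^{\,n-1}$)
  has birth $n$ forced male. The expected excess of boys per couple is
  $p^{\,n} \Pr(N \ge n)$ and the intervening-couple fraction is
  $\Phi = p^{\,n-1}\Pr(N \ge n)$.
* **Stopping rule** (`predict_stopping()`): couples stop childbearing once a
  son arrives, so sonless couples intervene only at their *last* birth, and
  only if their family size is at least $n$. A family of $N \ge n$ children
  intervenes iff its first $N-1$ births were all girls, giving the excess
  boys per couple as the partial exponential sum
  $$S(\lambda, n) = \sum_{N \ge n} \frac{\lambda^N e^{-\lambda}}{N!}\, p^N
    = e^{\lambda(p-1)} \Pr(M \ge n), \qquad M \sim \mathrm{Poisson}(\lambda p),$$
  and $\Phi = S/p$. The stopping rule is the variant that matches observed
  male-biased sex ratios at last birth and accommodates any combination of
  fertility and SRB levels; it is the default throughout.

Intervention is modelled as IVF-like — the designated birth is male with
certainty and family size is unchanged — so expected births per couple are
conserved: $E[\text{boys}] + E[\text{girls}] = \lambda$ always, with
$E[\text{boys}] = \lambda(1-p) + S$. The SRB follows as
$R = E[\text{boys}]/E[\text{girls}]$, reported canonically as the proportion
of births male (`r_prop`) and conventionally as boys per 100 girls
(`r_b100g`). If intervention is instead implemented by sex-selective
abortion, the birth-sex distribution is unchanged; only the count of
intervention events differs (below).

$\Phi$ counts *all* couples in its denominator, childless couples included.
The companion quantity $\Psi = \Phi / (1 - e^{-\lambda})$ counts parents
only, and matters because rising childlessness at low $\lambda$ could
otherwise be suspected of driving the results.

## The two peaks and the disproportionality effect

As fertility falls, the chance of remaining sonless by chance rises
(the fertility squeeze), so both $R(\lambda)$ and $\Phi(\lambda)$ rise as
$\lambda$ decreases — until so many families fall short of the threshold
that both collapse toward the no-intervention limit. Each therefore has an
interior maximum. `peak_over_lambda()` locates it with a coarse grid
(step 0.05 over $(0, 20]$, so an interior peak cannot be missed between
brackets) followed by `stats::optimize()` to an absolute $\lambda$ tolerance
of $10^{-4}$; a quantity that is monotone on the interval (e.g. $\Phi$ under
the universal rule at $n=1$, which is simply $1 - e^{-\lambda}$) is reported
as a boundary solution with a warning.

Running the default model (computed by the test suite and
`scripts/acceptance.R`): for $n = 2$, $p = 0.486$, the SRB peaks at 130.6
boys per 100 girls near $\lambda \approx 1.217$, while $\Phi$ peaks at 19.5%
of couples near $\lambda \approx 2.49$. The SRB keeps rising over a whole
fertility range in which the proportion of intervening couples is already
*falling* — the model's central result, and the reason SRB trends cannot be
read as sex-selection trends. The gap survives when childless couples are
excluded ($\Psi$'s peak sits close to $\Phi$'s), so it is not a
childlessness artefact. The remaining mechanism is the
**disproportionality effect**: at fixed $\Phi$, inverting the birth
accounting gives
$$R(\lambda, \Phi) = \frac{\lambda(1-p) + p\Phi}{\lambda p - p\Phi},$$
which increases steeply as $\lambda$ falls — the same number of
sex-converted births weighs more in a smaller birth cohort
(`srb_at_fixed_phi()`).

## Estimating propensity from observed data

Solving the same balance for $\Phi$ given an observed SRB $r$ (boys per
girl) and fertility $\lambda$ gives the estimator behind
`phi_from_observation()` and `batch_estimate()`:
$$\Phi = \frac{\lambda\,(p r - (1 - p))}{p\,(1 + r)}.$$
This is algebraically exact against the stopping-rule forward model for
every $(\lambda, n)$ — the round-trip identity is tested to $10^{-9}$ — and
requires no choice of $n$: $\Phi$ is an effective population propensity.
Design choices made here, where the design was genuinely open:

* The reported total fertility rate is used directly as $\lambda$, a
  completed-family-size proxy; this is an approximation and is documented as
  such.
* An observed SRB at or below the natural benchmark returns $\Phi = 0$ with
  a `below_benchmark` flag and the signed raw solution kept for diagnostics
  (female-favouring bias is outside the model); an implied $\Phi > 1$ is
  flagged `implausible`.
* `batch_estimate()` overlays an ordinary-least-squares line of $\Phi$ on
  SRB across records — the "expected propensity given the SRB" under the
  average cross-record relationship. OLS is our choice; implausible rows
  are excluded from the fit but retained, flagged, in the output. With a
  single usable record (or no SRB spread) the fitted value is the record
  itself and the residual is zero.
* SRB units must be declared (`b100g` or proportion male), never inferred:
  a 1.06-versus-106 confusion would corrupt every estimate silently.

## The cohort simulator

`simulate_cohort()` implements the micro rules literally — draw
$N \sim \mathrm{Poisson}(\lambda)$ per couple, then each birth a girl with
probability $p$, then apply the intervention rule — and is the independent
oracle for every closed form: at $10^6$ couples the analytic SRB and $\Phi$
agree with the simulation within three Monte Carlo standard errors over a
grid of $\lambda \in \{0.5, 1, 2, 4\}$, $n \in \{1,\dots,4\}$, both
variants. Draw order is fixed (all family sizes, then all natural birth
sexes in couple order, then abortion counts where applicable), so a seed
reproduces a cohort bit for bit. Standard errors are delta-method: binomial
for $\hat\Phi$, ratio-estimator over per-couple counts for the SRB.

`simulate_abortion_variant()` replaces the preconception mechanism with
diagnosis-and-abortion: an intervening couple re-conceives until a male
fetus, so abortions per intervening couple are geometric with mean
$p/(1-p) = 0.946$ at the default benchmark — slightly *below* the one
intervention per couple a preconception method implies, which is the sense
in which the two mechanisms involve a similar number of interventions. The
package asserts the geometric mean and the $0.946$ ratio exactly, not a
spurious equality.

`generate_observation_table()` produces synthetic national/state-style
(TFR, SRB) series with the true $\Phi$ recorded per row. Deterministic mode
uses the closed forms (estimator recovery to $10^{-9}$); noisy mode
simulates a finite cohort per row (default $10^5$ couples in the recovery
tests), records the *realised* TFR and SRB, and stores a per-row
delta-method standard error `se_phi` so recovery can be asserted at
$3\,\mathrm{SE}$. Rows specified by $\Phi$ rather than $n$ select
intervening couples among parents with probability
$\Psi = \Phi/(1-e^{-\lambda})$ and force their last birth male, so the
expected all-couple intervening fraction is exactly $\Phi$; a $\Phi$
exceeding the parent fraction is an error.

What the generator emulates is the *sampling* structure of reported series
— finite cohorts, Poisson family sizes, binomial sexes under the stated
rules. Real national series additionally carry registration error,
heterogeneous son preference and access, parity-specific behaviour beyond
the sonless rule, and period-vs-cohort fertility mismatch; passing the
recovery tests therefore shows the estimator is consistent under the
model's own assumptions, not that those assumptions hold in any particular
country's data.

## Numerical choices

* Poisson tails via `ppois(..., lower.tail = FALSE)`; the stopping-rule sum
  via the identity $S = e^{\lambda(p-1)}\Pr(\mathrm{Poisson}(\lambda p) \ge n)$
  — no naive $1 - \mathrm{cdf}$ subtraction anywhere. Explicit pmf
  truncation (in `family_size_pmf()`) keeps tail mass below $10^{-12}$.
* $\Psi$ uses `-expm1(-lambda)` for small-$\lambda$ accuracy.
* $\lambda = 0$ returns zero births and $\Phi = 0$ with the SRB undefined
  (`NA`); a hypothetical over-intervention regime ($E[\text{girls}] \le 0$)
  is returned flagged `degenerate` with an infinite SRB rather than raised,
  so $\lambda$-scans can cross it — under the two implemented rules it is
  in fact unreachable for $\lambda > 0$, which the tests assert.
* Problem sizes: oracle cohorts default to $10^6$ couples (seconds per
  cell), unit tests use $10^4$–$10^5$, noisy recovery rows $10^5$.

## Known limitations

Couples are homogeneous in $p$ and in preference; there are no mixtures of
son-preferring and indifferent couples beyond what the effective $\Phi$
absorbs, no parity-specific SRB decomposition, no covariates, no temporal
dynamics within a cohort, and no uncertainty intervals on $\Phi$ from the
sampling variability of a reported SRB (a natural next step). The threshold
$n$ itself is not estimable from a single (SRB, TFR) pair.
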