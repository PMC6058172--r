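test_that("the same seed reproduces a cohort bit for bit", {
  a <- simulate_cohort(5e3, 2.2, model_spec("stopping", 2), seed = 7,
                       keep_families = TRUE)
  b <- simulate_cohort(5e3, 2.2, model_spec("stopping", 2), seed = 7,
                       keep_families = TRUE)
  expect_identical(a, b)
  c <- simulate_cohort(5e3, 2.2, model_spec("stopping", 2), seed = 8)
  expect_false(identical(a$total_boys, c$total_boys))
})

test_that("simulated families obey the intervention rules", {
  for (variant in c("universal", "stopping")) {
    sim <- simulate_cohort(2e3, 2.5, model_spec(variant, 2),
                           seed = 11, keep_families = TRUE)
    fam <- sim$families
    expect_equal(nchar(fam$sexes), fam$n_children)
    expect_equal(vapply(gregexpr("B", fam$sexes, fixed = TRUE), function(g)
      sum(g > 0), numeric(1)), as.numeric(fam$n_boys))
    expect_equal(sum(fam$intervened), sim$n_interventions)
    hit <- fam[fam$intervened, ]
    expect_true(nrow(hit) > 0)
    # the intervened birth is a boy and all prior births are girls
    forced <- substr(hit$sexes, hit$intervention_order, hit$intervention_order)
    expect_true(all(forced == "B"))
    prior <- substr(hit$sexes, 1, hit$intervention_order - 1)
    expect_false(any(grepl("B", prior)))
    if (variant == "universal") {
      expect_true(all(hit$intervention_order == 2))
    } else {
      expect_true(all(hit$intervention_order == hit$n_children))
      # non-intervening multi-child families never end sonless after all-girl runs
      miss <- fam[!fam$intervened & fam$n_children >= 2, ]
      expect_false(any(grepl("^G+$", miss$sexes)))
    }
  }
})

test_that("cohort aggregates are internally consistent", {
  sim <- simulate_cohort(2e4, 1.8, model_spec("stopping", 2), seed = 3)
  expect_equal(sim$total_boys + sim$total_girls, sim$total_births)
  expect_equal(sim$phi_hat, sim$n_interventions / sim$n_couples)
  expect_equal(sim$srb_b100g, 100 * sim$total_boys / sim$total_girls)
  expect_gt(sim$psi_hat, sim$phi_hat)  # parents are a subset of couples
})

test_that("simulated cohorts agree with the closed forms", {
  for (variant in c("universal", "stopping")) {
    for (cell in list(c(1, 2), c(2.5, 1), c(2.5, 3))) {
      lam <- cell[1]; n <- cell[2]
      pred <- predict_family_model(lam, model_spec(variant, n))
      sim <- simulate_cohort(1e5, lam, model_spec(variant, n), seed = 101)
      lab <- sprintf("%s lambda=%g n=%d", variant, lam, n)
      expect_lt(abs(sim$srb_b100g - pred$r_b100g), 3 * sim$se_srb, label = lab)
      expect_lt(abs(sim$phi_hat - pred$phi),
                3 * max(sim$se_phi, 1e-6), label = lab)
    }
  }
})

test_that("a childless cohort yields empty aggregates", {
  sim <- simulate_cohort(100, 0, model_spec("stopping", 2), seed = 1)
  expect_equal(sim$total_births, 0)
  expect_equal(sim$n_interventions, 0)
  expect_true(is.na(sim$srb_b100g))
})

test_that("sonless stopping makes the last birth male-biased", {
  sim <- simulate_cohort(1e5, 2.5, model_spec("stopping", 2), seed = 5)
  expect_gt(sim$phi_hat, 0)
  expect_gt(sim$last_birth_srb, sim$earlier_birth_srb)
})

test_that("the abortion mechanism reproduces the geometric intervention count", {
  # at p = 0.5 the geometric mean is exactly 1 abortion per intervening couple
  sim <- simulate_abortion_variant(5e4, 2.5, model_spec("stopping", 2),
                                   params = natural_params(0.5), seed = 13)
  se_mean <- sim$se_abortions / sim$n_interventions
  expect_lt(abs(sim$mean_abortions_per_intervener - 1), 3 * se_mean)

  # birth outcomes identical in distribution to the preconception run
  pre <- simulate_cohort(5e4, 2.5, model_spec("stopping", 2),
                         params = natural_params(0.5), seed = 13)
  expect_identical(sim$total_boys, pre$total_boys)
  expect_identical(sim$n_interventions, pre$n_interventions)

  # no couple reaches a huge threshold: no interveners, no abortions
  none <- simulate_abortion_variant(1e3, 1, model_spec("stopping", 30), seed = 2)
  expect_equal(none$n_interventions, 0)
  expect_equal(none$n_abortions, 0)
})

test_that("deterministic observation tables round-trip through the estimator", {
  sc <- data.frame(label = c("a", "b", "c"), lambda = c(1.5, 2.5, 4),
                   phi = c(0, 0.1, NA), n = c(NA, NA, 2))
  tbl <- generate_observation_table(sc, mode = "deterministic")
  bench <- natural_srb()$boys_per_100_girls
  expect_equal(tbl$srb[1], bench, tolerance = 1e-12)  # phi = 0 row
  out <- batch_estimate(tbl)
  expect_equal(out$phi, tbl$phi_true, tolerance = 1e-9)
})

test_that("noisy observation tables recover ground truth within sampling error", {
  sc <- data.frame(label = c("n2-lo", "n2-hi", "phi-mid"),
                   lambda = c(2, 3.5, 2.5),
                   phi = c(NA, NA, 0.12), n = c(2, 2, NA))
  tbl <- generate_observation_table(sc, seed = 21, mode = "noisy",
                                    cohort_size = 2e4)
  out <- batch_estimate(tbl)
  expect_true(all(abs(out$phi - tbl$phi_true) < 3 * tbl$se_phi))
})

test_that("scenario validation rejects conflicting or empty specifications", {
  expect_error(generate_observation_table(
    data.frame(label = "x", lambda = 2, phi = 0.1, n = 2)), "not both")
  expect_error(generate_observation_table(
    data.frame(label = "x", lambda = 2, phi = NA, n = NA)), "one of")
  expect_error(generate_observation_table(data.frame()), "empty")
  # phi beyond the parent fraction is impossible to realise
  expect_error(generate_observation_table(
    data.frame(label = "x", lambda = 0.1, phi = 0.5, n = NA),
    seed = 1, mode = "noisy", cohort_size = 100), "parent fraction")
})
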