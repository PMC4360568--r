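test_that("meiotic transmission halves the load in expectation", {
  empty <- sim_individual(c(0, 0, 0))
  set.seed(1)
  g <- transmit_gamete(empty)
  expect_equal(sum(g$per_system_counts), 0)

  parent <- sim_individual(c(4, 2, 2), x_count = 2)
  set.seed(2)
  draws <- replicate(1e5, sum(transmit_gamete(parent)$per_system_counts))
  se <- sqrt(8 * 0.25 / 1e5)
  expect_true(within_3se(mean(draws), 4, se))
})

test_that("zygote formation adds Poisson(N) mutations placed by system size", {
  arch <- genome_architecture(4, c(8000, 6000, 4000, 2000))
  p0 <- model_params(M = 7, N = 0)
  empty <- list(per_system_counts = rep(0L, 4), x_count = 0L)
  set.seed(3)
  z <- form_zygote(empty, empty, p0, arch)
  expect_equal(z$total_load, 0)

  p1 <- model_params(M = 7, N = 1)
  set.seed(4)
  zygs <- replicate(2e4, form_zygote(empty, empty, p1, arch)$per_system_counts)
  expect_true(within_3se(mean(colSums(zygs)), 1, sqrt(1 / 2e4)))
  # multinomial oracle: system frequencies proportional to sizes
  sys_totals <- rowSums(zygs)
  n_total <- sum(sys_totals)
  for (s in 1:4) {
    expect_true(within_3se(sys_totals[s] / n_total, arch$share[s],
                           sqrt(arch$share[s] * (1 - arch$share[s]) / n_total)))
  }
})

test_that("zygote formation rejects mismatched architectures", {
  arch <- genome_architecture(3, c(2000, 2000, 2000))
  g2 <- list(per_system_counts = rep(0L, 2), x_count = 0L)
  g3 <- list(per_system_counts = rep(0L, 3), x_count = 0L)
  expect_error(form_zygote(g2, g3, model_params(), arch),
               class = "mutload_contract_error")
})

test_that("viability tiers follow the per-system rule", {
  rule <- selection_rule()
  expect_equal(classify_viability(sim_individual(c(4, 0, 0)), rule),
               "lethal_conception")
  expect_equal(classify_viability(sim_individual(c(7, 0, 0)), rule),
               "lethal_conception")
  for (i in 1:20) {
    expect_equal(classify_viability(sim_individual(c(1, 1, 0)), rule),
                 "survivor")
  }
  certain <- selection_rule(q3 = 1, q2 = 1)
  expect_equal(classify_viability(sim_individual(c(3, 0, 0)), certain),
               "postnatal_death")
  # non-essential systems are exempt from the rule
  arch <- genome_architecture(2, c(2000, 2000),
                              essential_flags = c(TRUE, FALSE))
  expect_equal(classify_viability(sim_individual(c(0, 9)), rule, arch),
               "survivor")
  expect_error(selection_rule(q3 = 0.1, q2 = 0.5),
               class = "mutload_domain_error")
})

test_that("without selection the mean load grows by N per generation", {
  none <- selection_rule(lethal_threshold = Inf, q3 = 0, q2 = 0)
  s <- run_generations(model_params(M = 4, N = 1),
                       genome_architecture(), none,
                       pop_size = 1000, n_generations = 50, seed = 5)
  # expectation 4 + 50; band covers accumulated genetic drift
  # (resampling adds ~ var/pop per generation: sd ~ 1.2 over 50)
  expect_lt(abs(tail(s$mean_adult_load, 1) - 54), 4)
  expect_true(all(s$zygote_loss_fraction == 0))
  expect_true(all(s$postnatal_death_fraction == 0))
})

test_that("the default synergy rule keeps the mean adult load bounded", {
  s <- run_generations(model_params(M = 7, N = 1),
                       genome_architecture(), selection_rule(),
                       pop_size = 1000, n_generations = 120, seed = 6)
  expect_true(all(s$zygote_loss_fraction >= 0 &
                  s$zygote_loss_fraction <= 1))
  # far below the no-selection drift M0 + g*N
  expect_lt(tail(s$mean_adult_load, 1), 7 + 120 * 1 / 2)
  eq <- equilibrium_summary(s)
  expect_true(is.finite(eq$M_eq))
  expect_gt(eq$loss_eq, 0)
})

test_that("identical seeds give bit-identical series", {
  a <- run_generations(model_params(), pop_size = 200,
                       n_generations = 10, seed = 42)
  b <- run_generations(model_params(), pop_size = 200,
                       n_generations = 10, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_generations(model_params(), pop_size = 200,
                       n_generations = 10, seed = 43)
  expect_false(identical(a$mean_adult_load, c$mean_adult_load))
})

test_that("extinction raises a solver error carrying partial stats", {
  harsh <- selection_rule(lethal_threshold = 1, q3 = 0, q2 = 0)
  expect_error(
    run_generations(model_params(M = 20, N = 5), genome_architecture(),
                    harsh, pop_size = 100, n_generations = 5, seed = 7),
    class = "mutload_solver_error")
})

test_that("equilibrium summary averages the final third", {
  const <- data.frame(generation = 1:120, mean_adult_load = 7,
                      zygote_loss_fraction = 0.2,
                      postnatal_death_fraction = 0.1,
                      population_size = 1000)
  eq <- equilibrium_summary(const)
  expect_equal(eq$M_eq, 7)
  expect_equal(eq$loss_eq, 0.2)
  expect_equal(eq$postnatal_eq, 0.1)
  expect_equal(eq$M_eq_se, 0)
  expect_error(equilibrium_summary(const[1:50, ]),
               class = "mutload_contract_error")
})

test_that("the loss-fraction sweep reports one row per rule setting", {
  sw <- sweep_loss_fraction(model_params(M = 7, N = 1),
                            q3_values = c(0.1, 0.5), q2_values = 0.05,
                            pop_size = 300, n_generations = 100, seed = 8)
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$loss_eq > 0 & sw$loss_eq < 1))
  expect_true(all(is.finite(sw$M_eq)))
})
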