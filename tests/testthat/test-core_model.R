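test_that("zygote load pmf matches the exact-factorial Poisson oracle", {
  for (lambda in c(0.5, 2, 8, 12)) {
    d <- zygote_load_pmf(model_params(M = lambda, N = 0))
    k <- 0:min(30, d$k_max)
    expect_equal(d$pmf[k + 1], poisson_pmf_oracle(k, lambda),
                 tolerance = 1e-10)
  }
  # spot value quoted against the oracle: P(k = 8) at mean 8
  d <- zygote_load_pmf(model_params(M = 7, N = 1))
  expect_equal(d$pmf[9], exp(-8) * 8^8 / factorial(8), tolerance = 1e-10)
})

test_that("zygote load pmf is a valid distribution with mean M + N", {
  for (M in c(0, 2, 7)) {
    for (N in c(0, 0.5, 1)) {
      d <- zygote_load_pmf(model_params(M = M, N = N))
      expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
      expect_true(all(d$pmf >= 0))
      expect_equal(d$mean, M + N, tolerance = 1e-9)
      expect_equal(sum(d$k * d$pmf), d$mean, tolerance = 1e-12)
      expect_false(d$truncated)
    }
  }
  degen <- zygote_load_pmf(model_params(M = 0, N = 0))
  expect_equal(degen$pmf[1], 1)
  expect_equal(degen$mean, 0)
})

test_that("model parameters are validated", {
  expect_error(model_params(M = -1), class = "mutload_domain_error")
  expect_error(model_params(N = -0.5), class = "mutload_domain_error")
  expect_error(model_params(x_fraction_haploid = 1.2),
               class = "mutload_domain_error")
})

test_that("truncation equilibrium reproduces the direct-summation oracle", {
  sol <- solve_truncation_equilibrium(model_params(M = 7, N = 1))
  oracle <- truncation_loss_oracle(7, 1)
  expect_equal(sol$k_star, oracle$k_star)
  expect_equal(sol$accept_at_k_star, oracle$accept, tolerance = 1e-9)
  expect_equal(sol$loss_fraction, oracle$loss, tolerance = 1e-9)
  # frozen values from the pre-build oracle runs (exact summation and a
  # 2e6-draw Monte-Carlo trim both give 0.1914)
  expect_equal(sol$k_star, 10)
  expect_equal(sol$loss_fraction, 0.1913787, tolerance = 1e-6)
  expect_equal(sol$accept_at_k_star, 0.9268145, tolerance = 1e-6)
})

test_that("zero mutational input yields the identity solution", {
  sol <- solve_truncation_equilibrium(model_params(M = 5, N = 0))
  expect_equal(sol$loss_fraction, 0)
  expect_true(is.infinite(sol$k_star))
  d <- zygote_load_pmf(model_params(M = 5, N = 0))
  expect_identical(apply_selection(d, sol), d)
})

test_that("selection restores the adult mean to M across the grid", {
  for (M in c(2, 4, 7, 10)) {
    for (N in c(0.25, 0.5, 1, 2)) {
      p <- model_params(M = M, N = N)
      sol <- solve_truncation_equilibrium(p)
      adult <- apply_selection(zygote_load_pmf(p), sol)
      expect_equal(adult$mean, M, tolerance = 1e-9)
      expect_equal(sum(adult$pmf), 1, tolerance = 1e-12)
      expect_true(adult$truncated)
      expect_equal(adult$k_max, sol$k_star)
    }
  }
})

test_that("zygote loss increases with the mutational input", {
  for (M in c(2, 5, 7, 10)) {
    losses <- vapply(c(0.25, 0.5, 1, 1.5, 2), function(N) {
      solve_truncation_equilibrium(model_params(M = M, N = N))$loss_fraction
    }, numeric(1))
    expect_true(all(diff(losses) > 0))
  }
})

test_that("selection solver and application reject invalid input", {
  expect_error(solve_truncation_equilibrium(model_params(), tol = 0),
               class = "mutload_domain_error")
  expect_error(apply_selection(list(), solve_truncation_equilibrium(model_params())),
               class = "mutload_contract_error")
  narrow <- zygote_load_pmf(model_params(M = 0.5, N = 0.5))
  wide_sol <- solve_truncation_equilibrium(model_params(M = 20, N = 5))
  expect_error(apply_selection(narrow, wide_sol),
               class = "mutload_contract_error")
})

test_that("the X chromosome carries M/40 of the diploid load", {
  expect_equal(x_linked_expected_load(model_params(M = 7)), 7 / 40)
  expect_equal(x_linked_expected_load(model_params(M = 0)), 0)
  expect_equal(x_linked_expected_load(model_params(M = 40)), 1)
  # male-lethal X alleles scale the expectation down
  expect_equal(x_linked_expected_load(model_params(M = 7),
                                      male_viability = 0.8), 0.14)
})

test_that("pmf TSV export pads the adult column above the truncation", {
  p <- model_params(M = 7, N = 1)
  zyg <- zygote_load_pmf(p)
  adult <- apply_selection(zyg, solve_truncation_equilibrium(p))
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- export_load_distributions(zyg, adult, f)
  back <- read.delim(f)
  expect_equal(back, out, tolerance = 1e-12)
  expect_true(all(back$p_adult[back$k > 10] == 0))
  expect_equal(sum(back$p_zygote), 1, tolerance = 1e-12)
})
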