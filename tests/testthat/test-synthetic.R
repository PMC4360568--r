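test_that("population cohorts match their Poisson moments", {
  empty <- simulate_population(model_params(), n = 0, seed = 1)
  expect_equal(nrow(empty), 0)

  co <- simulate_population(model_params(M = 7), n = 1e5, seed = 2)
  expect_equal(nrow(co), 1e5)
  expect_true(within_3se(mean(co$load), 7, sqrt(7 / 1e5)))
  # X-linked share of the load: E[x_count]/E[load] = 1/40
  ratio <- mean(co$x_count) / mean(co$load)
  se_ratio <- sqrt(1 / 40 * (1 - 1 / 40) / sum(co$load))
  expect_true(within_3se(ratio, 1 / 40, se_ratio))
  expect_true(all(co$sex %in% c("male", "female")))
})

test_that("cousin cohorts reproduce the closed-form disease fraction", {
  none <- simulate_cousin_cohort(0, n = 1000, seed = 3)
  expect_true(all(!none$disease))

  co <- simulate_cousin_cohort(7, n = 2e4, seed = 4)
  expected <- 1 - exp(-7 / 32)
  se <- sqrt(expected * (1 - expected) / 2e4)
  expect_true(within_3se(mean(co$disease), expected, se))
  expect_equal(co$disease, co$autozygous_load >= 1)
})

test_that("estimate_M recovers the generating load from a cohort", {
  co <- simulate_cousin_cohort(7, n = 2e4, seed = 5)
  f <- mean(co$disease)
  se <- sqrt(f * (1 - f) / nrow(co))
  ci <- estimate_M(min(f + 1.96 * se, 1 - 1e-12))
  ci_lo <- estimate_M(max(f - 1.96 * se, 0))
  expect_true(ci_lo <= 7 && 7 <= ci)
})

test_that("case/control cohorts hit the attribution-model rates", {
  co <- simulate_case_control(0.25, 3, n_cases = 2e4, n_controls = 2e4,
                              seed = 6)
  cases <- co[co$group == "case", ]
  controls <- co[co$group == "control", ]
  expect_true(within_3se(mean(cases$carrier), 0.5, sqrt(0.25 / 2e4)))
  expect_true(within_3se(mean(controls$carrier), 0.25,
                         sqrt(0.25 * 0.75 / 2e4)))
  # null model: rr = 1 makes the groups exchangeable
  null <- simulate_case_control(0.25, 1, 2e4, 2e4, seed = 7)
  nc <- mean(null$carrier[null$group == "case"])
  nk <- mean(null$carrier[null$group == "control"])
  expect_true(within_3se(nc, 0.25, sqrt(0.25 * 0.75 / 2e4)))
  expect_true(within_3se(nk, 0.25, sqrt(0.25 * 0.75 / 2e4)))
})

test_that("generators are deterministic under their echoed parameters", {
  for (make in list(
    function(s) simulate_population(model_params(), 500, seed = s),
    function(s) simulate_cousin_cohort(7, 500, seed = s),
    function(s) simulate_case_control(0.25, 3, 250, 250, seed = s)
  )) {
    a <- make(11)
    b <- make(11)
    expect_identical(as.data.frame(a), as.data.frame(b))
    p <- attr(a, "generator_params")
    expect_equal(p$seed, 11)
  }
})

test_that("cohort TSV round-trips records and parameters", {
  co <- simulate_cousin_cohort(7, 200, seed = 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, f)
  expect_true(startsWith(readLines(f, n = 1), "# kind: cousin_offspring"))
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(co))
  expect_equal(attr(back, "kind"), "cousin_offspring")
  p <- attr(back, "generator_params")
  expect_equal(p$M, 7)
  expect_equal(p$seed, 12)
  # regenerating from the echoed parameters reproduces the records
  again <- simulate_cousin_cohort(p$M, p$n, seed = p$seed)
  expect_equal(as.data.frame(again), as.data.frame(back))
})
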