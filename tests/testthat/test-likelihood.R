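test_that("forward recursion equals hidden-path enumeration", {
  withr::local_seed(1)
  for (r in 1:6) {
    params <- random_params()
    kerns <- action_kernels(params, backend = "exact")
    for (T_len in 1:4) {
      s <- random_series(T_len)
      expect_equal(forward_loglik(s, params, kerns),
                   brute_force_loglik(s, params, kerns), tolerance = 1e-10)
    }
  }
})

test_that("degenerate emissions give closed-form likelihoods", {
  params <- species_params(
    list(WC = lht(0.3, 0.5, 2), OR = lht(0.3, 0.5, 2),
         M = lht(0.3, 0.5, 2), SF = lht(0.3, 0.5, 2)),
    p0 = c(1, 0, 0, 0, 0, 0))
  kerns <- action_kernels(params, backend = "exact")
  # empty bank emits absence surely: P(c_x^1 = 1) = 1
  expect_equal(forward_loglik(field_series("f", "WC", 1), params, kerns), 0)
  # uniform kernels: any T-series has probability 4^-T
  uk <- list(WC = uniform_kernel(), OR = uniform_kernel(),
             M = uniform_kernel(), SF = uniform_kernel())
  withr::local_seed(2)
  for (T_len in c(1, 3, 5)) {
    s <- random_series(T_len)
    expect_equal(forward_loglik(s, params, uk), -T_len * log(4),
                 tolerance = 1e-12)
    if (T_len <= 4)
      expect_equal(brute_force_loglik(s, params, uk), -T_len * log(4),
                   tolerance = 1e-12)
  }
})

test_that("impossible observation sequences hit the likelihood floor", {
  params <- species_params(
    list(WC = lht(0, 0.5, 2), OR = lht(0, 0.5, 2),
         M = lht(0, 0.5, 2), SF = lht(0, 0.5, 2)),
    p0 = c(0.5, 0.5, 0, 0, 0, 0))
  kerns <- action_kernels(params, backend = "exact")
  s <- field_series("f", c("WC", "M"), c(1, 3))  # emergence impossible
  expect_equal(forward_loglik(s, params, kerns), -1e10)
  expect_equal(brute_force_loglik(s, params, kerns), -1e10)
})

test_that("total log-likelihood decomposes over independent series", {
  withr::local_seed(3)
  params <- random_params()
  kerns <- action_kernels(params, backend = "exact")
  series <- lapply(1:20, function(i)
    random_series(sample(1:5, 1), id = paste0("F", i)))
  ds <- survey_dataset(series)
  per_series <- vapply(series, forward_loglik, numeric(1),
                       params = params, kernels = kerns)
  expect_equal(total_loglik(ds, params), sum(per_series), tolerance = 1e-10)
  # one series reduces to forward_loglik
  expect_equal(total_loglik(survey_dataset(series[1]), params),
               per_series[1], tolerance = 1e-12)
  # duplication doubles; order is irrelevant
  expect_equal(total_loglik(survey_dataset(c(series, series)), params),
               2 * sum(per_series), tolerance = 1e-10)
  expect_equal(total_loglik(survey_dataset(rev(series)), params),
               sum(per_series), tolerance = 1e-10)
  # empty dataset carries no information
  expect_equal(total_loglik(survey_dataset(list()), params), 0)
})

test_that("exact-backend likelihood is reproducible, mc-backend seeded", {
  withr::local_seed(4)
  params <- random_params()
  ds <- survey_dataset(lapply(1:5, function(i)
    random_series(3, id = paste0("F", i))))
  clear_kernel_cache()
  a <- total_loglik(ds, params, backend = "exact")
  clear_kernel_cache()
  expect_identical(a, total_loglik(ds, params, backend = "exact"))
  clear_kernel_cache()
  m1 <- total_loglik(ds, params, backend = "mc", K = 2000, mc_seed = 9)
  clear_kernel_cache()
  m2 <- total_loglik(ds, params, backend = "mc", K = 2000, mc_seed = 9)
  expect_identical(m1, m2)
})

test_that("missing kernels and oversized enumerations are caught", {
  params <- random_params()
  kerns <- action_kernels(params, backend = "exact")[c("WC", "M")]
  s <- field_series("f", c("WC", "OR"), c(1, 1))
  expect_error(forward_loglik(s, params, kerns), "no kernel")
  long <- field_series("f", rep("WC", 8), rep(1, 8))
  expect_error(brute_force_loglik(long, params,
                                  action_kernels(params, backend = "exact")),
               "guarded")
})
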