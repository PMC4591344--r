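test_that("kernels are row-stochastic with sane supports", {
  withr::local_seed(1)
  for (r in 1:5) {
    l <- lht(runif(1), runif(1), runif(1, 0, 40))
    for (k in list(exact_kernel(l), estimate_kernel_mc(l, K = 5000))) {
      expect_true(all(k$emergence >= 0 & k$emergence <= 1))
      expect_true(all(abs(rowSums(k$emergence) - 1) < 1e-9))
      for (cy in 1:6) for (cx in 1:4)
        expect_lt(abs(sum(k$bank_update[cy, cx, ]) - 1), 1e-9)
      # empty bank is absorbing: no emergence, bank stays empty
      expect_equal(k$emergence[1, 1], 1)
      expect_equal(k$bank_update[1, 1, 1], 1)
    }
  }
})

test_that("no germination means no emergence, exactly", {
  for (backend in c("exact", "mc")) {
    k <- if (backend == "exact") exact_kernel(lht(0, 0.6, 12))
         else estimate_kernel_mc(lht(0, 0.6, 12), K = 2000, seed = 2)
    expect_equal(k$emergence[, 1], rep(1, 6))
    expect_true(all(k$emergence[, 2:4] == 0))
  }
  # sigma = 0, s = 1: the bank class never changes
  k <- exact_kernel(lht(0, 1, 12))
  for (cy in 1:6) expect_equal(k$bank_update[cy, 1, cy], 1)
})

test_that("two-seed bank emergence matches the closed form", {
  # c_y = 2: Y uniform on {1, 2}; P(X'=0) = (1/2)(1-s)... with sigma = 0.5:
  # P(c_x'=1) = (0.5 + 0.25)/2 = 0.375, P(c_x'=2) = 0.625
  ke <- exact_kernel(lht(0.5, 0.5, 1))
  expect_equal(ke$emergence[2, 1], 0.375, tolerance = 1e-12)
  expect_equal(ke$emergence[2, 2], 0.625, tolerance = 1e-12)
  km <- estimate_kernel_mc(lht(0.5, 0.5, 1), K = 30000, seed = 3)
  se <- sqrt(0.375 * 0.625 / 30000)
  expect_lt(abs(km$emergence[2, 1] - 0.375), 3 * se)
})

test_that("deterministic unit production returns each germinated seed", {
  # sigma = 1, phi = 1: all Y seeds emerge and each returns one seed
  k <- exact_kernel(lht(1, 0.5, 1), production = "deterministic")
  expect_equal(k$bank_update[2, 2, 2], 1)  # Y in {1,2} -> Y' = Y
  expect_equal(k$emergence[2, 2], 1)
})

test_that("probability of zero emergence is non-increasing in bank class", {
  withr::local_seed(4)
  for (r in 1:5) {
    l <- lht(runif(1, 0.01, 0.99), runif(1), runif(1, 0, 30))
    k <- exact_kernel(l)
    expect_true(all(diff(k$emergence[, 1]) <= 1e-12))
  }
})

test_that("Monte-Carlo and exact kernels agree within sampling error", {
  withr::local_seed(5)
  for (r in 1:4) {
    l <- lht(runif(1), runif(1), runif(1, 0, 30))
    ke <- exact_kernel(l)
    km <- estimate_kernel_mc(l, K = 30000, seed = r)
    expect_lt(max(abs(ke$emergence - km$emergence)), 0.012)
    # compare bank updates through the joint law P(c_x', c_y' | c_y)
    je <- jm <- array(0, c(6, 4, 6))
    for (cy in 1:6) for (cx in 1:4) {
      je[cy, cx, ] <- ke$emergence[cy, cx] * ke$bank_update[cy, cx, ]
      jm[cy, cx, ] <- km$emergence[cy, cx] * km$bank_update[cy, cx, ]
    }
    expect_lt(max(abs(je - jm)), 0.012)
  }
})

test_that("zero-support cells are uniform-filled and masked", {
  k <- exact_kernel(lht(0, 0.5, 3))  # no emergence: c_x' > 1 unreachable
  expect_false(any(k$support[, 2:4]))
  expect_true(all(k$bank_update[, 2:4, ] == 1 / 6))
  km <- estimate_kernel_mc(lht(0, 0.5, 3), K = 500, seed = 6)
  expect_false(any(km$support[, 2:4]))
})

test_that("only the open-ended top class feels the enumeration cap", {
  l <- lht(0.3, 0.7, 6)
  sch <- abundance_scheme()
  ks <- lapply(c(200, 300, 500), function(cap)
    exact_kernel(l, abundance_scheme(seedbank_top_cap = cap)))
  for (i in 2:3) {
    expect_equal(ks[[1]]$emergence[1:5, ], ks[[i]]$emergence[1:5, ],
                 tolerance = 1e-12)
    expect_equal(ks[[1]]$bank_update[1:5, , ], ks[[i]]$bank_update[1:5, , ],
                 tolerance = 1e-12)
  }
  # the top row varies smoothly, not wildly, with the cap
  expect_lt(max(abs(ks[[1]]$emergence[6, ] - ks[[3]]$emergence[6, ])), 0.25)
  expect_error(exact_kernel(l, cap = 50), "cap")
})

test_that("kernel memoisation returns identical tables", {
  clear_kernel_cache()
  l <- lht(0.21, 0.43, 7.5)
  k1 <- seedbankHMM:::cached_kernel(l, abundance_scheme(), "exact")
  k2 <- seedbankHMM:::cached_kernel(l, abundance_scheme(), "exact")
  expect_identical(k1, k2)
  expect_gt(clear_kernel_cache(), 0)
})

test_that("long-format export covers every cell once", {
  kerns <- action_kernels(study_truth(), backend = "exact")
  df <- kernels_to_df(kerns)
  expect_equal(nrow(df), 4 * (6 * 4 + 6 * 4 * 6))
  expect_true(all(df$probability >= 0 & df$probability <= 1))
  em <- df[df$table == "emergence" & df$action == "WC", ]
  expect_equal(sum(em$probability), 6, tolerance = 1e-9)
})
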