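test_that("the calibrated design matches the survey's reported structure", {
  d <- default_design()
  expect_equal(d$n_fields, 329L)
  expect_equal(sum(d$length_pmf), 1, tolerance = 1e-9)
  expect_equal(sum(d$action_freq), 1, tolerance = 1e-12)
  expect_equal(d$action_freq, c(0.496, 0.102, 0.293, 0.108) / 0.999)
  mu <- sum(d$length_pmf * d$lengths)
  sdv <- sqrt(sum(d$length_pmf * d$lengths^2) - mu^2)
  expect_equal(mu, 3.62, tolerance = 0.01)
  expect_equal(sdv, 1.19, tolerance = 0.05)
})

test_that("moment matching fails loudly only when infeasible", {
  p <- length_pmf_from_moments(2:8, 5, 0.8)
  expect_equal(sum(p * (2:8)), 5, tolerance = 1e-6)
  expect_equal(sqrt(sum(p * (2:8)^2) - 25), 0.8, tolerance = 1e-4)
})

test_that("generation is seed-reproducible and leak-free", {
  truth <- study_truth()
  g1 <- small_dataset(n_fields = 30, seed = 5, truth = truth)
  g2 <- small_dataset(n_fields = 30, seed = 5, truth = truth)
  expect_identical(g1$dataset, g2$dataset)
  expect_identical(g1$hidden, g2$hidden)
  g3 <- small_dataset(n_fields = 30, seed = 6, truth = truth)
  expect_false(identical(g1$dataset, g3$dataset))
  # hidden record round-trips: censoring the hidden plant counts
  # reproduces the observations exactly
  expect_equal(classify_count(g1$hidden$plants, abundance_scheme(),
                              "emerged"),
               g1$hidden$observed_class)
  obs <- unlist(lapply(g1$dataset$series, `[[`, "observations"))
  expect_equal(obs, g1$hidden$observed_class)
  # observable dataset carries classes only, never counts
  expect_null(g1$dataset$series[[1]]$plants)
})

test_that("no germination anywhere yields pure-absence surveys", {
  truth <- species_params(
    list(WC = lht(0, 0.5, 5), OR = lht(0, 0.9, 5),
         M = lht(0, 0.2, 5), SF = lht(0, 0.5, 5)),
    p0 = rep(1 / 6, 6))
  g <- small_dataset(n_fields = 25, seed = 8, truth = truth)
  expect_true(all(unlist(lapply(g$dataset$series, `[[`,
                                "observations")) == 1L))
})

test_that("a full-size draw realises the design frequencies", {
  g <- generate_dataset(study_truth(), default_design(), seed = 42)
  expect_equal(length(g$dataset$series), 329L)
  tl <- vapply(g$dataset$series, function(s) length(s$observations),
               integer(1))
  expect_true(all(tl >= 2 & tl <= 8))
  expect_lt(abs(mean(tl) - 3.62), 0.2)
  acts <- unlist(lapply(g$dataset$series, `[[`, "actions"))
  freq <- as.vector(table(factor(acts, default_actions()))) / length(acts)
  expect_true(all(abs(freq - c(0.496, 0.102, 0.293, 0.108) / 0.999) < 0.03))
})

test_that("markov rotations honour the supplied transition matrix", {
  P <- matrix(c(0, 1, 0, 0,
                0, 0, 1, 0,
                0, 0, 0, 1,
                1, 0, 0, 0), 4, 4, byrow = TRUE)  # deterministic rotation
  d <- study_design(15, length_pmf_from_moments(2:8, 3.62, 1.19), 2:8,
                    c(0.25, 0.25, 0.25, 0.25), rotation = "markov",
                    rotation_matrix = P)
  g <- generate_dataset(study_truth(), d, seed = 3)
  idx <- c(WC = 1, OR = 2, M = 3, SF = 4)
  for (s in g$dataset$series) {
    a <- idx[s$actions]
    if (length(a) > 1)
      expect_true(all(diff(a) %% 4 == 1 | diff(a) == -3))
  }
  expect_error(study_design(10, length_pmf_from_moments(2:8, 3.62, 1.19),
                            2:8, rep(0.25, 4), rotation = "markov"),
               "rotation_matrix")
})
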