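test_that("efficiencies and signed class errors match hand computation", {
  m <- compute_metrics(predicted = c(1, 2, 1), observed = c(1, 1, 1))
  expect_equal(m$absence_efficiency, 2 / 3)
  expect_equal(m$class_error_absence$mean, 1)   # predicted 2, observed 1
  expect_true(is.na(m$presence_efficiency))     # no presence observed
  expect_true(is.na(m$class_error_presence$mean))

  m <- compute_metrics(predicted = c(2, 3), observed = c(3, 4))
  expect_equal(m$presence_efficiency, 1)        # above-1 predicted above-1
  expect_equal(m$class_error_presence$mean, -1) # under-prediction: negative

  # all-correct absences leave the error cell undefined, never 0
  m <- compute_metrics(predicted = rep(1, 5), observed = rep(1, 5))
  expect_equal(m$absence_efficiency, 1)
  expect_true(is.na(m$class_error_absence$mean))

  # a presence predicted as absence counts against presence efficiency
  m <- compute_metrics(predicted = c(1, 1, 4), observed = c(2, 3, 4))
  expect_equal(m$presence_efficiency, 1 / 3)
  expect_equal(m$class_error_presence$mean, mean(c(-1, -2)))
})

test_that("metrics are permutation-invariant and bounded by extremes", {
  withr::local_seed(1)
  obs <- sample(1:4, 60, replace = TRUE)
  pred <- sample(1:4, 60, replace = TRUE)
  m1 <- compute_metrics(pred, obs)
  perm <- sample(60)
  m2 <- compute_metrics(pred[perm], obs[perm])
  expect_equal(m1$absence_efficiency, m2$absence_efficiency)
  expect_equal(m1$class_error_presence$mean, m2$class_error_presence$mean)
  perfect <- compute_metrics(obs, obs)
  expect_equal(perfect$absence_efficiency, 1)
  expect_equal(perfect$presence_efficiency, 1)
  wrong <- compute_metrics(ifelse(obs == 1, 2, 1), obs)
  expect_equal(wrong$absence_efficiency, 0)
  expect_equal(wrong$presence_efficiency, 0)
})

test_that("fields partition into near-equal reproducible folds", {
  f <- seedbankHMM:::fold_assignment(329, 4, seed = 1)
  expect_equal(sort(as.vector(table(f)), decreasing = TRUE),
               c(83, 82, 82, 82))
  expect_equal(length(f), 329)
  expect_identical(f, seedbankHMM:::fold_assignment(329, 4, seed = 1))
  expect_false(identical(f, seedbankHMM:::fold_assignment(329, 4, seed = 2)))
  expect_error(seedbankHMM:::fold_assignment(3, 4), "fewer fields")
})

test_that("next-class prediction respects degenerate structures", {
  # empty bank with no seed production predicts absence forever
  params <- species_params(
    list(WC = lht(0.6, 0.5, 0), OR = lht(0.6, 0.5, 0),
         M = lht(0.6, 0.5, 0), SF = lht(0.6, 0.5, 0)),
    p0 = c(1, 0, 0, 0, 0, 0))
  kerns <- action_kernels(params, backend = "exact")
  for (t_len in 0:3) {
    pr <- predict_next_class(rep(1L, t_len), rep("WC", t_len + 1L),
                             params, kerns)
    expect_equal(pr$class, 1L)
  }
  # uniform kernels: tie broken toward the smallest class
  uk <- list(WC = uniform_kernel(), OR = uniform_kernel(),
             M = uniform_kernel(), SF = uniform_kernel())
  pr <- predict_next_class(c(2L, 3L), c("WC", "M", "SF"), params, uk)
  expect_equal(pr$class, 1L)
  expect_equal(pr$distribution, rep(0.25, 4))
  # zero-probability prefix warns and falls back to the prior
  zp <- species_params(
    list(WC = lht(0, 0.5, 2), OR = lht(0, 0.5, 2),
         M = lht(0, 0.5, 2), SF = lht(0, 0.5, 2)),
    p0 = c(0.5, 0.5, 0, 0, 0, 0))
  zk <- action_kernels(zp, backend = "exact")
  expect_warning(predict_next_class(c(3L), c("WC", "WC"), zp, zk),
                 "probability zero")
})

test_that("predictions track simulations under strongly peaked dynamics", {
  truth <- study_truth()
  g <- small_dataset(n_fields = 60, seed = 21, truth = truth)
  kerns <- action_kernels(truth, backend = "exact")
  pred <- obs <- integer(0)
  for (s in g$dataset$series) {
    for (k in seq_along(s$observations)) {
      pr <- predict_next_class(s$observations[seq_len(k - 1L)],
                               s$actions[seq_len(k)], truth, kerns)
      pred <- c(pred, pr$class)
      obs <- c(obs, s$observations[k])
    }
  }
  # at the generating parameters the modal prediction beats chance clearly
  expect_gt(mean(pred == obs), 0.4)
  m <- compute_metrics(pred, obs)
  expect_gt(m$absence_efficiency, 0.7)
})

test_that("species filters enforce the survey-count and pair rules", {
  expect_equal(select_species(data.frame(field_id = character(0),
                                         year = integer(0),
                                         action = character(0),
                                         species_id = character(0),
                                         abundance_class = integer(0))),
               character(0))
  # one species present in 119 surveys, one in 120: only the latter stays
  mk <- function(sp, n, action = "WC") data.frame(
    field_id = paste0("f", seq_len(n)), year = 2000L, action = action,
    species_id = sp, abundance_class = 2L)
  rec <- rbind(mk("A", 119), mk("B", 120))
  expect_equal(select_species(rec, min_pair_fraction = 0), "B")
  # pair rule: species C present under one action only is dropped
  base <- expand.grid(field_id = paste0("f", 1:120),
                      year = 2000L, stringsAsFactors = FALSE)
  base$action <- rep(c("WC", "M"), 60)
  recC <- cbind(base, species_id = "C",
                abundance_class = ifelse(base$action == "WC", 2L, 1L))
  recD <- cbind(base, species_id = "D", abundance_class = 2L)
  expect_equal(select_species(rbind(recC, recD)), "D")
})

test_that("an engineered community keeps exactly the intended species", {
  withr::local_seed(2)
  n_fields <- 150
  fields <- paste0("f", seq_len(n_fields))
  actions <- rep(c("WC", "M"), length.out = n_fields)
  rows <- list()
  for (i in 1:32) {
    sp <- sprintf("SP%02d", i)
    keep <- i <= 18
    n_pres <- if (keep) 130 else 60  # below the 120-survey threshold
    idx <- sample(n_fields, n_pres)
    rows[[i]] <- data.frame(field_id = fields[idx], year = 2000L + (i %% 3),
                            action = actions[idx], species_id = sp,
                            abundance_class = 3L)
  }
  got <- select_species(do.call(rbind, rows), min_pair_fraction = 0.10)
  expect_equal(got, sprintf("SP%02d", 1:18))
})

test_that("cross-validation aggregates held-out one-step predictions", {
  g <- small_dataset(n_fields = 24, seed = 31)
  rep1 <- cross_validate(g$dataset, n_folds = 3,
                         fit_control = search_control(
                           population_size = 40, max_iterations = 30,
                           refine_cycles = 0, polish = FALSE, seed = 1),
                         seed = 5)
  expect_equal(sum(rep1$fold_sizes), 24)
  expect_equal(rep1$n_predictions,
               sum(vapply(g$dataset$series, function(s)
                 length(s$observations), integer(1))))
  expect_true(rep1$metrics$absence_efficiency >= 0 &&
                rep1$metrics$absence_efficiency <= 1)
  df <- cv_report_to_df(rep1, "syn")
  expect_equal(nrow(df), 1)
  expect_error(cross_validate(g$dataset, n_folds = 40), "fewer fields")
})
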