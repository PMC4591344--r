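#' One-step-ahead prediction of the emerged abundance class
#'
#' Predicts the next emerged-plant class as the mode of its predictive
#' distribution under the fitted model. In `"filtered"` mode (default) the
#' seed-bank class distribution is obtained by running the forward filter
#' over the whole observed prefix, then propagated through the bank-update
#' and emergence tables of the next action. In `"single_step"` mode the
#' filter is re-initialised from `p0` at every step, so the prediction
#' conditions on the latest observation only. Ties in the predictive
#' distribution are broken toward the smallest class. A prefix of
#' probability zero raises a warning and falls back to propagating the
#' prior `p0`.
#'
#' @param observations integer vector of observed classes (length t >= 0).
#' @param actions character vector of actions of length t + 1: the actions
#'   leading to each observed survey followed by the action of the season
#'   whose survey is being predicted.
#' @param params a [species_params()].
#' @param kernels per-action kernels, see [action_kernels()].
#' @param mode `"filtered"` or `"single_step"`.
#' @return List with `class` (the predicted class) and `distribution` (the
#'   predictive pmf over emerged classes).
#' @export
predict_next_class <- function(observations, actions, params, kernels,
                               mode = c("filtered", "single_step")) {
  mode <- match.arg(mode)
  t_len <- length(observations)
  if (length(actions) != t_len + 1L)
    stop("need length(actions) == length(observations) + 1")
  a <- match(actions, names(kernels))
  if (any(is.na(a)))
    stop("no kernel available for some action")
  KY <- length(params$p0)

  bank_dist <- if (t_len == 0L) {
    params$p0
  } else if (mode == "single_step") {
    a_prev <- a[t_len]
    cx <- observations[t_len]
    E <- kernels[[a_prev]]$emergence
    B <- kernels[[a_prev]]$bank_update
    w <- numeric(KY)
    for (cy in seq_len(KY))
      w <- w + params$p0[cy] * E[cy, cx] * B[cy, cx, ]
    if (sum(w) <= 0) {
      warning("observed prefix has probability zero; falling back to p0")
      params$p0
    } else w / sum(w)
  } else {
    alpha <- params$p0 * kernels[[a[1L]]]$emergence[, observations[1L]]
    ok <- TRUE
    if (t_len >= 2L) for (s in 2:t_len) {
      if (sum(alpha) <= 0) { ok <- FALSE; break }
      alpha <- alpha / sum(alpha)
      B <- kernels[[a[s - 1L]]]$bank_update
      alpha <- as.vector(crossprod(B[, observations[s - 1L], ], alpha)) *
        kernels[[a[s]]]$emergence[, observations[s]]
    }
    if (!ok || sum(alpha) <= 0) {
      warning("observed prefix has probability zero; falling back to p0")
      params$p0
    } else {
      alpha <- alpha / sum(alpha)
      # move from c_y^{t-1} to c_y^t through the last step's bank update
      as.vector(crossprod(kernels[[a[t_len]]]$bank_update[, observations[t_len], ],
                          alpha))
    }
  }

  pred <- as.vector(crossprod(kernels[[a[t_len + 1L]]]$emergence, bank_dist))
  pred <- pred / sum(pred)
  list(class = which.max(pred), distribution = pred)
}

#' Absence/presence predictive efficiency and class errors
#'
#' Computes the four cells of the cross-validation report from paired
#' predicted and observed class sequences: the efficiency for absence is
#' the proportion of observed class-1 positions predicted as class 1; the
#' efficiency for presence the proportion of observed class-above-1
#' positions predicted above 1. The class attribution errors are averaged
#' over *incorrect* predictions only, signed as predicted minus observed,
#' separately for the absence and presence strata; a stratum with no
#' (incorrect) member yields `NA` ("n.a."), never a silent 0. The
#' parenthetical spread reported alongside each error is the standard error
#' of the mean.
#'
#' @param predicted,observed equal-length integer class vectors.
#' @return A list of class `cv_metrics`: `absence_efficiency`,
#'   `presence_efficiency`, `class_error_absence` / `class_error_presence`
#'   (each a list with `mean`, `se`, `sd`, `n`), and stratum counts
#'   `n_absence`, `n_presence`.
#' @examples
#' compute_metrics(predicted = c(1, 2, 1), observed = c(1, 1, 1))
#' @export
compute_metrics <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  abs_idx <- observed == 1L
  pres_idx <- observed > 1L
  eff <- function(hit, n) if (n == 0L) NA_real_ else hit / n
  err_cell <- function(idx) {
    wrong <- idx & (predicted != observed)
    n <- sum(wrong)
    if (n == 0L)
      return(list(mean = NA_real_, se = NA_real_, sd = NA_real_, n = 0L))
    d <- predicted[wrong] - observed[wrong]
    list(mean = mean(d),
         se = if (n > 1L) stats::sd(d) / sqrt(n) else 0,
         sd = if (n > 1L) stats::sd(d) else 0, n = n)
  }
  structure(list(
    absence_efficiency = eff(sum(abs_idx & predicted == 1L), sum(abs_idx)),
    presence_efficiency = eff(sum(pres_idx & predicted > 1L), sum(pres_idx)),
    class_error_absence = err_cell(abs_idx),
    class_error_presence = err_cell(pres_idx),
    n_absence = sum(abs_idx), n_presence = sum(pres_idx)
  ), class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  fmt_eff <- function(e) if (is.na(e)) "n.a." else sprintf("%.3f", e)
  fmt_err <- function(c) if (is.na(c$mean)) "n.a."
                         else sprintf("%.2f (%.2f)", c$mean, c$se)
  cat("Predictive efficiency: absence", fmt_eff(x$absence_efficiency),
      "| presence", fmt_eff(x$presence_efficiency), "\n")
  cat("Class error:           absence", fmt_err(x$class_error_absence),
      "| presence", fmt_err(x$class_error_presence), "\n")
  invisible(x)
}

# Partition n field indices into near-equal folds: base size floor(n/k),
# the remainder going to the first folds; assignment by seeded shuffle.
fold_assignment <- function(n, n_folds, seed = 1L) {
  if (n < n_folds) stop("fewer fields than folds")
  sizes <- rep(n %/% n_folds, n_folds) +
    c(rep(1L, n %% n_folds), rep(0L, n_folds - n %% n_folds))
  perm <- withr::with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(n_folds), times = sizes)
  fold
}

#' K-fold cross-validated predictive efficiency
#'
#' Randomly partitions the fields into `n_folds` near-equal folds (any
#' remainder enlarging the first folds), refits the model on each training
#' complement with [fit_ml()], predicts every held-out observation one step
#' ahead with [predict_next_class()] (including the first survey, predicted
#' from `p0` alone), and aggregates [compute_metrics()] over all held-out
#' predictions.
#'
#' @param dataset a [survey_dataset()].
#' @param n_folds number of folds (default 4).
#' @param fit_control a [search_control()] for the per-fold fits.
#' @param seed integer seed controlling the fold assignment.
#' @inheritParams fit_ml
#' @param mode prediction mode, see [predict_next_class()].
#' @return A list of class `cv_report`: `metrics` (a `cv_metrics`), `folds`
#'   (assignment vector), `fold_sizes`, `n_predictions`, `fold_logliks`,
#'   `predicted`, `observed`.
#' @export
cross_validate <- function(dataset, n_folds = 4L,
                           fit_control = search_control(), seed = 1L,
                           scheme = abundance_scheme(),
                           backend = c("exact", "mc"), K = 30000L,
                           production = "poisson", mc_seed = 1L,
                           mode = "filtered") {
  backend <- match.arg(backend)
  n <- length(dataset$series)
  fold <- fold_assignment(n, n_folds, seed)
  predicted <- observed <- integer(0)
  fold_logliks <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    train <- survey_dataset(dataset$series[fold != f], dataset$species_id,
                            dataset$actions)
    fit <- fit_ml(train, bounds = default_bounds(actions = dataset$actions),
                  control = fit_control, scheme = scheme, backend = backend,
                  K = K, production = production, mc_seed = mc_seed)
    fold_logliks[f] <- fit$loglik
    kernels <- action_kernels(fit$params, scheme, backend, K, production,
                              mc_seed)
    for (s in dataset$series[fold == f]) {
      T_len <- length(s$observations)
      for (k in seq_len(T_len)) {
        pr <- predict_next_class(s$observations[seq_len(k - 1L)],
                                 s$actions[seq_len(k)], fit$params, kernels,
                                 mode = mode)
        predicted <- c(predicted, pr$class)
        observed <- c(observed, s$observations[k])
      }
    }
  }
  structure(list(metrics = compute_metrics(predicted, observed),
                 folds = fold, fold_sizes = as.vector(table(fold)),
                 n_predictions = length(predicted),
                 fold_logliks = fold_logliks,
                 predicted = predicted, observed = observed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation over", length(x$fold_sizes), "folds (sizes",
      paste(x$fold_sizes, collapse = "/"), "),",
      x$n_predictions, "held-out predictions\n")
  print(x$metrics)
  invisible(x)
}

#' Export a cross-validation report as a one-row data frame
#'
#' Columns follow the efficiency/error table layout: efficiencies for
#' absence and presence, class errors with their standard errors, and the
#' counts behind each cell; undefined cells are `NA` (printed as "n.a.").
#'
#' @param report a `cv_report` (or bare `cv_metrics`).
#' @param species_id identifier for the row.
#' @return A one-row data frame.
#' @export
cv_report_to_df <- function(report, species_id = "species") {
  m <- if (inherits(report, "cv_report")) report$metrics else report
  data.frame(species = species_id,
             n_absence = m$n_absence, n_presence = m$n_presence,
             absence_efficiency = m$absence_efficiency,
             presence_efficiency = m$presence_efficiency,
             class_error_absence = m$class_error_absence$mean,
             class_error_absence_se = m$class_error_absence$se,
             class_error_presence = m$class_error_presence$mean,
             class_error_presence_se = m$class_error_presence$se)
}

#' Species retention filters for a records table
#'
#' Applies the two dataset filters used before estimation: a species must
#' have been recorded (abundance class above 1) in at least `min_surveys`
#' surveys, and — among those retained — a species is dropped when, for any
#' management action in the table, the (species, action) pair is present in
#' fewer than `min_pair_fraction` of all crop sequences (field series).
#'
#' @param records a records data frame, see [read_records()].
#' @param min_surveys minimum number of presence records (default 120).
#' @param min_pair_fraction minimum fraction of fields in which each
#'   (species, action) pair must occur (default 0.10).
#' @return Sorted character vector of retained species ids.
#' @export
select_species <- function(records, min_surveys = 120L,
                           min_pair_fraction = 0.10) {
  if (nrow(records) == 0L) return(character(0))
  present <- records[records$abundance_class > 1L, , drop = FALSE]
  n_rec <- table(present$species_id)
  keep <- names(n_rec)[n_rec >= min_surveys]
  if (!length(keep)) return(character(0))
  n_fields <- length(unique(records$field_id))
  actions <- sort(unique(records$action))
  ok <- vapply(keep, function(sp) {
    rows <- present[present$species_id == sp, , drop = FALSE]
    frac <- vapply(actions, function(a)
      length(unique(rows$field_id[rows$action == a])) / n_fields, numeric(1))
    all(frac >= min_pair_fraction)
  }, logical(1))
  sort(keep[ok])
}
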