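LOGLIK_FLOOR <- -1e10

#' Forward log-likelihood of one field series
#'
#' Computes the log-probability of an observed sequence of emerged-plant
#' classes by the forward recursion over the hidden seed-bank classes:
#' `alpha(c_y^0) = p0(c_y^0) * E_{a^0}[c_y^0, c_x^1]`, then for t = 2..T
#' `alpha'(c_y^{t-1}) = sum_{c_y^{t-2}} alpha(c_y^{t-2}) *
#' B_{a^{t-2}}[c_y^{t-2}, c_x^{t-1}, c_y^{t-1}] * E_{a^{t-1}}[c_y^{t-1}, c_x^t]`,
#' and finally `log sum alpha`. The recursion is normalised at each step and
#' the accumulated log-scalers added back, so long series do not underflow.
#' A sequence of probability zero returns the floor value `-1e10` (so that
#' optimisers can still rank candidates).
#'
#' @param series a [field_series()].
#' @param params a [species_params()].
#' @param kernels named list of [transition_kernel] objects covering every
#'   action in the series (see [action_kernels()]).
#' @return The log-likelihood (scalar).
#' @export
forward_loglik <- function(series, params, kernels) {
  miss <- setdiff(unique(series$actions), names(kernels))
  if (length(miss))
    stop("no kernel available for action(s): ", paste(miss, collapse = ", "))
  obs <- series$observations
  T_len <- length(obs)
  a <- match(series$actions, names(kernels))
  alpha <- params$p0 * kernels[[a[1]]]$emergence[, obs[1]]
  logscale <- 0
  if (T_len >= 2) {
    for (t in 2:T_len) {
      tot <- sum(alpha)
      if (tot <= 0) return(LOGLIK_FLOOR)
      logscale <- logscale + log(tot)
      alpha <- alpha / tot
      B <- kernels[[a[t - 1]]]$bank_update
      E <- kernels[[a[t]]]$emergence
      alpha <- as.vector(crossprod(B[, obs[t - 1], ], alpha)) * E[, obs[t]]
    }
  }
  tot <- sum(alpha)
  if (tot <= 0) return(LOGLIK_FLOOR)
  logscale + log(tot)
}

#' Brute-force log-likelihood by hidden-path enumeration
#'
#' Evaluates the series probability as the explicit nested sum over all
#' hidden seed-bank class sequences `(c_y^0, ..., c_y^{T-1})`:
#' `L = sum P_{a^0}(c_x^1|c_y^0) p0(c_y^0) prod_{t=2}^{T}
#' P_{a^{t-2}}(c_y^{t-1}|c_x^{t-1}, c_y^{t-2}) P_{a^{t-1}}(c_x^t|c_y^{t-1})`.
#' Exponential in T; intended purely as a correctness oracle for
#' [forward_loglik()] on short series.
#'
#' @inheritParams forward_loglik
#' @param max_T guard on the series length (default 7; `6^T` terms).
#' @return The log-likelihood (scalar), `-1e10` for probability-0 sequences.
#' @export
brute_force_loglik <- function(series, params, kernels, max_T = 7L) {
  obs <- series$observations
  T_len <- length(obs)
  if (T_len > max_T)
    stop("brute-force enumeration guarded at T <= ", max_T)
  a <- match(series$actions, names(kernels))
  if (any(is.na(a)))
    stop("no kernel available for some action in the series")
  KY <- length(params$p0)
  paths <- as.matrix(expand.grid(rep(list(seq_len(KY)), T_len)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    cy <- paths[r, ]
    p <- params$p0[cy[1]] * kernels[[a[1]]]$emergence[cy[1], obs[1]]
    if (T_len >= 2) {
      for (t in 2:T_len) {
        p <- p * kernels[[a[t - 1]]]$bank_update[cy[t - 1], obs[t - 1], cy[t]] *
          kernels[[a[t]]]$emergence[cy[t], obs[t]]
      }
    }
    total <- total + p
  }
  if (total <= 0) LOGLIK_FLOOR else log(total)
}

#' Total log-likelihood of a survey dataset
#'
#' Sums [forward_loglik()] over the N independent field series, building
#' (and memoising) one transition kernel per management action from the
#' parameters. The `"exact"` backend is deterministic; the `"mc"` backend
#' reproduces the simulation-based kernel estimation, with common random
#' numbers (`mc_seed`) so the likelihood is a deterministic function of the
#' parameters for a fixed seed.
#'
#' @param dataset a [survey_dataset()].
#' @param params a [species_params()].
#' @inheritParams action_kernels
#' @return The total log-likelihood (scalar; 0 for an empty dataset).
#' @export
total_loglik <- function(dataset, params, scheme = abundance_scheme(),
                         backend = c("exact", "mc"), K = 30000L,
                         production = "poisson", mc_seed = 1L) {
  backend <- match.arg(backend)
  if (length(dataset$series) == 0L) return(0)
  packed <- pack_dataset(dataset, params$actions)
  total_loglik_packed(packed, params, scheme, backend, K, production, mc_seed)
}

# Same computation on a pre-packed dataset; the optimiser and the sampler
# pack once and call this in their inner loops.
total_loglik_packed <- function(packed, params, scheme = abundance_scheme(),
                                backend = "exact", K = 30000L,
                                production = "poisson", mc_seed = 1L) {
  if (length(packed$lens) == 0L) return(0)
  kernels <- action_kernels(params, scheme, backend, K, production, mc_seed)
  stacked <- stack_kernels(kernels)
  sum(forward_loglik_cpp(stacked$E, stacked$B, params$p0, packed$obs,
                         packed$act, packed$lens, LOGLIK_FLOOR))
}
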