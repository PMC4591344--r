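#' Class-level transition kernel of the hidden Markov model
#'
#' For one management action's trait triplet, the HMM needs two conditional
#' probability tables over abundance classes: the *emergence* table
#' `E[c_y, c_x']`, the probability that a bank in class `c_y` produces an
#' emerged-plant class `c_x'` the next year, and the *bank update* tensor
#' `B[c_y, c_x', c_y']`, the probability of the next bank class given the
#' current bank class and the realised emergence class. Both integrate the
#' count-level dynamics of [step_counts()] over the class intervals (counts
#' uniform within a class). [estimate_kernel_mc()] does this by Monte-Carlo
#' simulation with `K` draws per bank class — the procedure used on the real
#' survey data; [exact_kernel()] enumerates the count space exactly and is
#' both the deterministic inference backend and the oracle against which the
#' Monte-Carlo estimator is validated.
#'
#' Cells `(c_y, c_x')` that cannot occur (or were never simulated) get a
#' uniform `B` slice and are flagged `FALSE` in `support`; the likelihood
#' never weights such a slice because the corresponding emergence probability
#' is zero.
#'
#' @param lht an [lht()] trait triplet.
#' @param scheme an [abundance_scheme()].
#' @param K Monte-Carlo draws per seed-bank class (default 30000).
#' @param production `"poisson"` or `"deterministic"` seed rain, as in
#'   [step_counts()].
#' @param seed optional integer seed applied locally (MC estimator only).
#' @return An object of class `transition_kernel`: list with `emergence`
#'   (KY x KX matrix), `bank_update` (KY x KX x KY array), `support`
#'   (KY x KX logical), and the generating settings.
#' @examples
#' k <- exact_kernel(lht(0.3, 0.5, 5))
#' rowSums(k$emergence)
#' @name transition_kernel
NULL

new_transition_kernel <- function(emergence, bank_update, support, meta) {
  dimnames(emergence) <- NULL
  structure(list(emergence = emergence, bank_update = bank_update,
                 support = support, meta = meta),
            class = "transition_kernel")
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat("Transition kernel (", x$meta$method, ")\n", sep = "")
  cat("emergence P(c_x' | c_y):\n")
  print(round(x$emergence, 4))
  invisible(x)
}

#' @rdname transition_kernel
#' @export
estimate_kernel_mc <- function(lht, scheme = abundance_scheme(), K = 30000L,
                               production = c("poisson", "deterministic"),
                               seed = NULL) {
  production <- match.arg(production)
  stopifnot(K >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  KY <- n_classes(scheme, "seedbank")
  KX <- n_classes(scheme, "emerged")
  emergence <- matrix(0, KY, KX)
  bank <- array(1 / KY, dim = c(KY, KX, KY))
  support <- matrix(FALSE, KY, KX)
  for (cy in seq_len(KY)) {
    y0 <- sample_count_in_class(rep(cy, K), scheme, "seedbank")
    stepped <- step_counts(y0, lht, production)
    cx <- classify_count(stepped$plants, scheme, "emerged")
    cy2 <- classify_count(stepped$seeds, scheme, "seedbank")
    tab <- table(factor(cx, levels = seq_len(KX)),
                 factor(cy2, levels = seq_len(KY)))
    emergence[cy, ] <- rowSums(tab) / K
    for (cx_i in seq_len(KX)) {
      n_cx <- sum(tab[cx_i, ])
      if (n_cx > 0) {
        bank[cy, cx_i, ] <- tab[cx_i, ] / n_cx
        support[cy, cx_i] <- TRUE
      }
    }
  }
  new_transition_kernel(emergence, bank, support,
                        list(method = "mc", K = K, production = production,
                             lht = lht))
}

#' @rdname transition_kernel
#' @param cap integer truncation of the open-ended top seed-bank class for
#'   the exact enumeration; defaults to the scheme's `seedbank_top_cap`.
#' @export
exact_kernel <- function(lht, scheme = abundance_scheme(),
                         production = c("poisson", "deterministic"),
                         cap = scheme$seedbank_top_cap) {
  production <- match.arg(production)
  if (cap < scheme$seedbank_lower[n_classes(scheme, "seedbank")])
    stop("cap must not be smaller than the top seed-bank class lower bound")
  res <- exact_kernel_cpp(lht$sigma, lht$s, lht$phi,
                          as.integer(scheme$seedbank_lower), as.integer(cap),
                          as.integer(scheme$emerged_lower),
                          production == "poisson")
  new_transition_kernel(res$emergence, res$bank_update, res$support,
                        list(method = "exact", cap = cap,
                             production = production, lht = lht))
}

# ---- kernel cache -----------------------------------------------------------
# Kernels are memoised on the triplet (rounded to 12 decimals), scheme grid,
# backend and MC settings, so likelihood evaluations that share a triplet
# (coordinate-wise optimiser / sampler moves) reuse them.
.kernel_cache <- new.env(parent = emptyenv())

kernel_cache_key <- function(lht, scheme, backend, K, production, mc_seed) {
  paste(paste(sprintf("%.12g", c(lht$sigma, lht$s, lht$phi)), collapse = ","),
        paste(scheme$seedbank_lower, collapse = ","),
        paste(scheme$emerged_lower, collapse = ","),
        scheme$seedbank_top_cap, backend, K, production, mc_seed,
        sep = "|")
}

#' Clear the memoised kernel cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_kernel_cache <- function() {
  n <- length(ls(.kernel_cache))
  rm(list = ls(.kernel_cache), envir = .kernel_cache)
  invisible(n)
}

cached_kernel <- function(lht, scheme, backend = c("exact", "mc"),
                          K = 30000L, production = "poisson", mc_seed = 1L) {
  backend <- match.arg(backend)
  key <- kernel_cache_key(lht, scheme, backend, K, production, mc_seed)
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  kern <- if (backend == "exact") exact_kernel(lht, scheme, production)
          else estimate_kernel_mc(lht, scheme, K, production, seed = mc_seed)
  if (length(ls(.kernel_cache)) > 4096L) clear_kernel_cache()
  assign(key, kern, envir = .kernel_cache)
  kern
}

#' Build one kernel per management action
#'
#' @param params a [species_params()] object.
#' @param scheme an [abundance_scheme()].
#' @param backend `"exact"` (deterministic enumeration, default) or `"mc"`
#'   (Monte-Carlo with `K` draws and common random numbers fixed by
#'   `mc_seed`, making the resulting likelihood a deterministic function of
#'   the parameters).
#' @param K,production,mc_seed see [estimate_kernel_mc()].
#' @return Named list of `transition_kernel` objects, one per action.
#' @export
action_kernels <- function(params, scheme = abundance_scheme(),
                           backend = c("exact", "mc"), K = 30000L,
                           production = "poisson", mc_seed = 1L) {
  backend <- match.arg(backend)
  out <- lapply(params$lht, cached_kernel, scheme = scheme, backend = backend,
                K = K, production = production, mc_seed = mc_seed)
  names(out) <- params$actions
  out
}

#' Export kernels as a long-format data frame
#'
#' One row per (action, c_y, c_x', c_y') cell of the bank-update tensor and
#' one per (action, c_y, c_x') emergence cell, suitable for CSV inspection.
#'
#' @param kernels named list of kernels as returned by [action_kernels()].
#' @return A data frame with columns `action`, `table`, `c_y`, `c_x_next`,
#'   `c_y_next` (NA for emergence rows) and `probability`.
#' @export
kernels_to_df <- function(kernels) {
  rows <- lapply(names(kernels), function(a) {
    k <- kernels[[a]]
    KY <- nrow(k$emergence); KX <- ncol(k$emergence)
    em <- data.frame(action = a, table = "emergence",
                     c_y = rep(seq_len(KY), KX),
                     c_x_next = rep(seq_len(KX), each = KY),
                     c_y_next = NA_integer_,
                     probability = as.vector(k$emergence))
    bu <- data.frame(action = a, table = "bank_update",
                     c_y = rep(seq_len(KY), KX * KY),
                     c_x_next = rep(rep(seq_len(KX), each = KY), KY),
                     c_y_next = rep(seq_len(KY), each = KY * KX),
                     probability = as.vector(k$bank_update))
    rbind(em, bu)
  })
  do.call(rbind, rows)
}

# Stack per-action kernels into the flat arrays the C++ forward pass needs.
stack_kernels <- function(kernels) {
  KY <- nrow(kernels[[1]]$emergence)
  KX <- ncol(kernels[[1]]$emergence)
  A <- length(kernels)
  E <- array(0, dim = c(KY, KX, A))
  B <- array(0, dim = c(KY, KX, KY, A))
  for (i in seq_len(A)) {
    E[, , i] <- kernels[[i]]$emergence
    B[, , , i] <- kernels[[i]]$bank_update
  }
  list(E = E, B = B)
}
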