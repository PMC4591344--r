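# Parameter-vector packing and transforms shared by the ML search and the
# posterior sampler.
#
# Layout of the flat vector theta (natural scale):
#   for each action a (in order): sigma_a, s_a, phi_a
#   then the K-1 additive-log-ratio coordinates of p0 (last class = reference)

alr <- function(p, eps = 1e-12) {
  p <- pmax(p, eps)
  log(p[-length(p)] / p[length(p)])
}

alr_inv <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

theta_names <- function(actions, KY) {
  c(as.vector(t(outer(actions, c("sigma", "s", "phi"),
                      function(a, v) paste(v, a, sep = "_")))),
    paste0("alr", seq_len(KY - 1L)))
}

theta_to_params <- function(theta, actions, KY, phi_max = 200) {
  A <- length(actions)
  lhts <- vector("list", A)
  names(lhts) <- actions
  for (i in seq_len(A)) {
    o <- 3L * (i - 1L)
    lhts[[i]] <- lht(theta[o + 1L], theta[o + 2L], theta[o + 3L],
                     phi_max = phi_max)
  }
  p0 <- alr_inv(theta[(3L * A + 1L):(3L * A + KY - 1L)])
  species_params(lhts, p0)
}

params_to_theta <- function(params, KY = length(params$p0)) {
  c(unlist(lapply(params$lht, function(l) c(l$sigma, l$s, l$phi)),
    use.names = FALSE),
    alr(params$p0))
}

#' Default search/prior box for the parameter vector
#'
#' Lower and upper bounds used by [fit_ml()] (search box) and
#' [sample_posterior()] (support of the uniform prior): \[0, 1\] for every
#' sigma and s, \[0, `phi_max`\] for every phi, and \[-`alr_bound`,
#' `alr_bound`\] for the additive-log-ratio coordinates of `p0` (at 10 this
#' lets any single class carry from ~5e-5 to ~1-5e-5 of the mass).
#'
#' @param actions action labels.
#' @param n_seedbank_classes number of hidden classes (default 6).
#' @param phi_max upper bound on per-plant seed production (default 200).
#' @param alr_bound box half-width for the simplex coordinates (default 10).
#' @return List with numeric vectors `lower` and `upper` (named).
#' @export
default_bounds <- function(actions = default_actions(),
                           n_seedbank_classes = 6L, phi_max = 200,
                           alr_bound = 10) {
  A <- length(actions)
  nm <- theta_names(actions, n_seedbank_classes)
  lower <- c(rep(c(0, 0, 0), A), rep(-alr_bound, n_seedbank_classes - 1L))
  upper <- c(rep(c(1, 1, phi_max), A), rep(alr_bound, n_seedbank_classes - 1L))
  names(lower) <- names(upper) <- nm
  list(lower = lower, upper = upper, phi_max = phi_max, actions = actions,
       KY = as.integer(n_seedbank_classes))
}
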