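# Shared fixtures built in code.

# The ground-truth parameter set used for recovery experiments: four action
# triplets built from two contrasted life-history patterns (high-germination/
# low-survival winter strategy vs low-germination/high-survival persistence
# strategy), with distinct per-plant seed production so the across-action
# rank order of phi is testable. Growth rates sit near 1, as for arable
# weeds under management.
study_truth <- function() {
  species_params(
    list(WC = lht(0.45, 0.35, 2.2), OR = lht(0.10, 0.80, 3.0),
         M = lht(0.30, 0.50, 0.8), SF = lht(0.15, 0.60, 1.5)),
    p0 = c(0.30, 0.25, 0.25, 0.12, 0.05, 0.03))
}

# A small dataset for fast fitting tests.
small_dataset <- function(n_fields = 40, seed = 7, truth = study_truth()) {
  design <- study_design(n_fields,
                         length_pmf_from_moments(2:8, 3.62, 1.19), 2:8,
                         c(0.496, 0.102, 0.293, 0.108) / 0.999)
  generate_dataset(truth, design, seed = seed)
}

# Random valid parameter set (moderate phi so kernels stay informative).
random_params <- function(actions = default_actions(), phi_max = 30) {
  lhts <- lapply(actions, function(a) lht(runif(1), runif(1),
                                          runif(1, 0, phi_max)))
  names(lhts) <- actions
  p0 <- runif(6)
  species_params(lhts, p0 / sum(p0))
}

# Hand-built uniform kernel: every emergence row 1/4, every bank slice 1/6.
uniform_kernel <- function(KY = 6, KX = 4) {
  structure(list(emergence = matrix(1 / KX, KY, KX),
                 bank_update = array(1 / KY, c(KY, KX, KY)),
                 support = matrix(TRUE, KY, KX),
                 meta = list(method = "uniform")),
            class = "transition_kernel")
}

# Random series under a given action set.
random_series <- function(T_len, actions = default_actions(), id = "F1") {
  field_series(id, sample(actions, T_len, replace = TRUE),
               sample(1:4, T_len, replace = TRUE))
}

cli_path <- function() {
  system.file("cli", "seedbankhmm.R", package = "seedbankHMM")
}

run_cli <- function(args, dir) {
  out <- suppressWarnings(
    system2(file.path(R.home("bin"), "Rscript"),
            c(cli_path(), args, "--out", dir),
            stdout = TRUE, stderr = TRUE))
  attr(out, "status") %||% 0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
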