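#' Life-history trait triplet
#'
#' Bundles the three annual life-history traits of a therophyte weed under one
#' management action: the germination/establishment probability `sigma`, the
#' annual survival probability `s` of non-germinated seeds in the bank, and the
#' expected number `phi` of new seeds returned to the bank per emerged plant.
#'
#' @param sigma germination and establishment probability, in \[0, 1\].
#' @param s annual seed survival probability in the bank, in \[0, 1\].
#' @param phi expected seeds produced per emerged plant, in \[0, `phi_max`\].
#' @param phi_max upper bound accepted for `phi` (default 200).
#' @return An object of class `lht`.
#' @examples
#' lht(sigma = 0.3, s = 0.5, phi = 10)
#' @export
lht <- function(sigma, s, phi, phi_max = 200) {
  stopifnot(is.numeric(sigma), is.numeric(s), is.numeric(phi))
  if (sigma < 0 || sigma > 1) stop("sigma must lie in [0, 1]")
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  if (phi < 0 || phi > phi_max) stop("phi must lie in [0, phi_max]")
  structure(list(sigma = sigma, s = s, phi = phi), class = "lht")
}

#' @export
print.lht <- function(x, ...) {
  cat(sprintf("LHT: sigma = %.4g, s = %.4g, phi = %.4g\n", x$sigma, x$s, x$phi))
  invisible(x)
}

#' Default management action set
#'
#' The four crop-type management actions used throughout: winter cereals (WC),
#' oilseed rape (OR), maize (M) and sunflower (SF).
#'
#' @return Character vector of action labels.
#' @export
default_actions <- function() c("WC", "OR", "M", "SF")

#' Per-species parameter set
#'
#' Collects one [lht()] triplet per management action together with the
#' initial distribution `p0` of the seed-bank abundance class at time 0,
#' which is estimated alongside the traits rather than fixed a priori.
#'
#' @param lht_by_action named list of [lht()] objects, one per action label.
#' @param p0 probability vector over the seed-bank classes (sums to 1).
#' @return An object of class `species_params`.
#' @examples
#' species_params(
#'   lht_by_action = list(WC = lht(0.4, 0.5, 4), OR = lht(0.1, 0.7, 8),
#'                        M = lht(0.25, 0.4, 1), SF = lht(0.15, 0.55, 2)),
#'   p0 = c(0.35, 0.25, 0.2, 0.1, 0.06, 0.04)
#' )
#' @export
species_params <- function(lht_by_action, p0) {
  if (is.null(names(lht_by_action)) || any(!nzchar(names(lht_by_action))))
    stop("lht_by_action must be a named list (one LHT per action label)")
  if (!all(vapply(lht_by_action, inherits, logical(1), "lht")))
    stop("every element of lht_by_action must be an 'lht' object")
  p0 <- as.numeric(p0)
  if (any(p0 < 0)) stop("p0 entries must be non-negative")
  if (abs(sum(p0) - 1) > 1e-12) stop("p0 must sum to 1 (within 1e-12)")
  structure(list(lht = lht_by_action, p0 = p0, actions = names(lht_by_action)),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameters (", length(x$actions), " actions)\n", sep = "")
  for (a in x$actions)
    cat(sprintf("  %-4s sigma = %.3f  s = %.3f  phi = %.2f\n",
                a, x$lht[[a]]$sigma, x$lht[[a]]$s, x$lht[[a]]$phi))
  cat("  p0 =", paste(sprintf("%.3f", x$p0), collapse = " "), "\n")
  invisible(x)
}

#' One annual step of the count-level population dynamics
#'
#' Advances the count state (Y seeds in the bank, X emerged plants) by one
#' year under a trait triplet. Germination comes first: X' ~ Binomial(Y,
#' sigma) seeds emerge and establish. Among the Y - X' seeds left in the
#' bank, deaths follow Binomial(Y - X', 1 - s). Each emerged plant then
#' returns seeds to the bank: Poisson(phi * X') in `"poisson"` mode, or the
#' deterministic `round(phi * X')` in `"deterministic"` mode. Standing plants
#' never survive to the next year (annual species): the new plant count is
#' X' alone, and Y' = (Y - X' - dead) + new seeds.
#'
#' @param seeds non-negative integer seed-bank count Y (vectorised).
#' @param lht an [lht()] triplet.
#' @param production `"poisson"` (default) or `"deterministic"` seed-rain noise.
#' @param seed optional integer seed applied locally.
#' @return List with integer vectors `plants` (X') and `seeds` (Y').
#' @examples
#' step_counts(10, lht(1, 0.5, 0), seed = 1)   # all germinate, none return
#' @export
step_counts <- function(seeds, lht, production = c("poisson", "deterministic"),
                        seed = NULL) {
  production <- match.arg(production)
  if (any(seeds < 0)) stop("seed counts must be non-negative")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- length(seeds)
  emerged <- rbinom(n, seeds, lht$sigma)
  dead <- rbinom(n, seeds - emerged, 1 - lht$s)
  produced <- if (production == "poisson") rpois(n, lht$phi * emerged)
              else as.integer(round(lht$phi * emerged))
  list(plants = emerged, seeds = (seeds - emerged - dead) + produced)
}

#' One field's observed series
#'
#' A field contributes a sequence of T emerged-plant abundance classes
#' (observed at surveys 1..T) together with the T management actions of the
#' seasons leading up to each survey (actions indexed 0..T-1: the class
#' observed at survey t reflects emergence under action t-1).
#'
#' @param field_id identifier.
#' @param actions character vector of action labels, length T.
#' @param observations integer vector of emerged classes, length T.
#' @param n_emerged_classes number of classes on the emerged grid (default 4).
#' @return An object of class `field_series`.
#' @export
field_series <- function(field_id, actions, observations, n_emerged_classes = 4L) {
  observations <- as.integer(observations)
  if (length(actions) != length(observations) || length(observations) < 1L)
    stop("actions and observations must have equal length T >= 1")
  if (any(observations < 1L | observations > n_emerged_classes))
    stop("observations must be classes in 1..", n_emerged_classes)
  structure(list(field_id = field_id, actions = as.character(actions),
                 observations = observations),
            class = "field_series")
}

#' A species' survey dataset
#'
#' A collection of [field_series()] treated as independent samples for one
#' species; fields are the replication unit of the likelihood.
#'
#' @param series list of [field_series()] objects (N >= 1; may be empty only
#'   for prior-sampling checks).
#' @param species_id identifier.
#' @param actions the action set the series refer to.
#' @return An object of class `survey_dataset`.
#' @export
survey_dataset <- function(series, species_id = "species",
                           actions = default_actions()) {
  if (!all(vapply(series, inherits, logical(1), "field_series")))
    stop("series must be a list of field_series objects")
  used <- unique(unlist(lapply(series, `[[`, "actions")))
  if (!all(used %in% actions))
    stop("series use actions outside the action set: ",
         paste(setdiff(used, actions), collapse = ", "))
  structure(list(species_id = species_id, series = series, actions = actions),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  tl <- vapply(x$series, function(s) length(s$observations), integer(1))
  cat("Survey dataset '", x$species_id, "': ", length(x$series),
      " field series, ", sum(tl), " observations",
      if (length(tl)) sprintf(" (T = %d..%d, mean %.2f)", min(tl), max(tl), mean(tl)),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.survey_dataset <- function(x) length(x$series)

# Pack a dataset into flat integer vectors for the C++ forward pass.
# Actions become 1-based indices into `actions`.
pack_dataset <- function(dataset, actions = dataset$actions) {
  obs <- unlist(lapply(dataset$series, `[[`, "observations"))
  act <- unlist(lapply(dataset$series, function(s) match(s$actions, actions)))
  if (any(is.na(act))) stop("series contain actions missing from the kernel set")
  lens <- vapply(dataset$series, function(s) length(s$observations), integer(1))
  list(obs = as.integer(obs), act = as.integer(act), lens = as.integer(lens))
}
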