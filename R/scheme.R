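#' Abundance-class censoring scheme
#'
#' Defines the two ordinal grids used to censor counts per square metre into
#' semi-quantitative abundance classes: the 4-class Barralis-type scale for
#' emerged plants (1 = absent, 2 = 1-2, 3 = 3-20, 4 = more than 20) and the
#' extended 6-class scale for the soil seed bank (the open-ended top emerged
#' class is subdivided into 21-60, 61-100 and more than 100 seeds).
#'
#' Each grid is given by the ordered vector of lower bounds of its classes;
#' intervals are contiguous, start at 0 and jointly cover all non-negative
#' integers, the last class being open-ended. When a count has to be *drawn*
#' from the open-ended top class (Monte-Carlo kernel estimation, synthetic
#' data) the interval is truncated at `top_cap`.
#'
#' @param emerged_lower integer vector of class lower bounds for emerged
#'   plants; default `c(0, 1, 3, 21)`.
#' @param seedbank_lower integer vector of class lower bounds for the seed
#'   bank; default `c(0, 1, 3, 21, 61, 101)`.
#' @param emerged_top_cap,seedbank_top_cap integer substituted for +Inf as the
#'   upper bound of the top class when sampling counts; must strictly exceed
#'   the top class lower bound. Defaults 100 and 300.
#' @return An object of class `abundance_scheme`.
#' @examples
#' sch <- abundance_scheme()
#' classify_count(c(0, 2, 20, 21), sch, "emerged")
#' classify_count(150, sch, "seedbank")
#' @export
abundance_scheme <- function(emerged_lower = c(0L, 1L, 3L, 21L),
                             seedbank_lower = c(0L, 1L, 3L, 21L, 61L, 101L),
                             emerged_top_cap = 100L,
                             seedbank_top_cap = 300L) {
  check_lower <- function(lo, cap, what) {
    lo <- as.integer(lo)
    if (length(lo) < 2L || lo[1L] != 0L || any(diff(lo) <= 0L))
      stop(what, " class lower bounds must start at 0 and be strictly increasing")
    if (cap <= lo[length(lo)])
      stop(what, " top_cap must strictly exceed the top class lower bound")
    lo
  }
  obj <- list(
    emerged_lower = check_lower(emerged_lower, emerged_top_cap, "emerged"),
    seedbank_lower = check_lower(seedbank_lower, seedbank_top_cap, "seedbank"),
    emerged_top_cap = as.integer(emerged_top_cap),
    seedbank_top_cap = as.integer(seedbank_top_cap)
  )
  class(obj) <- "abundance_scheme"
  obj
}

#' @export
print.abundance_scheme <- function(x, ...) {
  fmt <- function(lo, cap) {
    hi <- c(lo[-1L] - 1L, NA)
    lab <- ifelse(is.na(hi), paste0("{", lo, ":+Inf, cap ", cap, "}"),
                  ifelse(lo == hi, paste0("{", lo, "}"),
                         paste0("{", lo, ":", hi, "}")))
    paste(lab, collapse = " ")
  }
  cat("Abundance-class scheme\n")
  cat("  emerged  (", length(x$emerged_lower), " classes): ",
      fmt(x$emerged_lower, x$emerged_top_cap), "\n", sep = "")
  cat("  seedbank (", length(x$seedbank_lower), " classes): ",
      fmt(x$seedbank_lower, x$seedbank_top_cap), "\n", sep = "")
  invisible(x)
}

scheme_lower <- function(scheme, which) {
  which <- match.arg(which, c("emerged", "seedbank"))
  if (which == "emerged") scheme$emerged_lower else scheme$seedbank_lower
}

scheme_cap <- function(scheme, which) {
  which <- match.arg(which, c("emerged", "seedbank"))
  if (which == "emerged") scheme$emerged_top_cap else scheme$seedbank_top_cap
}

#' Number of classes in one grid of a scheme
#'
#' @param scheme an [abundance_scheme()].
#' @param which `"emerged"` or `"seedbank"`.
#' @return Integer number of classes.
#' @export
n_classes <- function(scheme, which = c("emerged", "seedbank")) {
  length(scheme_lower(scheme, match.arg(which)))
}

#' Censor counts into abundance classes
#'
#' Maps non-negative integer counts to the ordinal class whose interval
#' contains them, on either grid of the scheme.
#'
#' @param count vector of non-negative integer counts.
#' @inheritParams n_classes
#' @return Integer vector of class indices (1-based).
#' @export
classify_count <- function(count, scheme = abundance_scheme(),
                           which = c("emerged", "seedbank")) {
  if (any(count < 0)) stop("counts must be non-negative")
  lo <- scheme_lower(scheme, match.arg(which))
  findInterval(count, lo)
}

#' Draw a count uniformly within an abundance class
#'
#' Inverse of [classify_count()] in distribution: draws integers uniformly
#' from the class interval, the open-ended top class being truncated at the
#' scheme's `top_cap`. Used by the Monte-Carlo kernel estimator and the
#' synthetic-data generator to integrate over a class range.
#'
#' @param class_index vector of class indices; recycled against `n`.
#' @param n number of draws (default `length(class_index)`).
#' @inheritParams n_classes
#' @param seed optional integer seed applied locally.
#' @return Integer vector of counts with `classify_count(result) == class_index`.
#' @export
sample_count_in_class <- function(class_index, scheme = abundance_scheme(),
                                  which = c("emerged", "seedbank"),
                                  n = length(class_index), seed = NULL) {
  which <- match.arg(which)
  lo <- scheme_lower(scheme, which)
  k <- length(lo)
  if (any(class_index < 1L | class_index > k))
    stop("class index out of range 1..", k)
  if (!is.null(seed)) withr::local_seed(seed)
  class_index <- rep_len(as.integer(class_index), n)
  hi <- c(lo[-1L] - 1L, scheme_cap(scheme, which))
  a <- lo[class_index]
  b <- hi[class_index]
  a + floor(runif(n) * (b - a + 1))
}
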