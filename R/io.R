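RECORD_COLUMNS <- c("field_id", "year", "action", "species_id",
                    "abundance_class")

#' Read and validate a survey records table
#'
#' A records CSV has one row per (field, year, species) with a header naming
#' the five columns `field_id`, `year`, `action`, `species_id`,
#' `abundance_class`. Years must be integers, emerged classes integers in
#' 1..`n_emerged_classes`, and (field, year, species) combinations unique;
#' violations are reported with their row numbers.
#'
#' @param path CSV file path.
#' @param n_emerged_classes valid class range upper end (default 4).
#' @return The validated records data frame.
#' @export
read_records <- function(path, n_emerged_classes = 4L) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(RECORD_COLUMNS, names(tab))
  if (length(miss))
    stop("records file is missing column(s): ", paste(miss, collapse = ", "))
  tab <- tab[RECORD_COLUMNS]
  bad_year <- which(is.na(tab$year) | tab$year != as.integer(tab$year))
  if (length(bad_year))
    stop("non-integer year in row(s): ",
         paste(head(bad_year, 5L), collapse = ", "))
  cls <- tab$abundance_class
  bad_cls <- which(is.na(cls) | cls != as.integer(cls) | cls < 1L |
                     cls > n_emerged_classes)
  if (length(bad_cls))
    stop("abundance_class outside 1..", n_emerged_classes, " in row(s): ",
         paste(head(bad_cls, 5L), collapse = ", "))
  key <- paste(tab$field_id, tab$year, tab$species_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (field_id, year, species_id) in row(s): ",
         paste(head(which(duplicated(key)), 5L), collapse = ", "))
  tab$year <- as.integer(tab$year)
  tab$abundance_class <- as.integer(tab$abundance_class)
  tab
}

#' Write a records table to CSV
#'
#' Inverse of [read_records()]: `read_records(write_records(tab, f))`
#' restores the table.
#'
#' @param records a records data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  write.csv(records[RECORD_COLUMNS], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Flatten a generated dataset into a records table
#'
#' @param dataset a [survey_dataset()].
#' @param species_id species label for the rows (default the dataset's).
#' @param start_year calendar year assigned to each field's first survey.
#' @return A records data frame. The action stored at year y is the action
#'   of the season culminating in the survey of year y.
#' @export
dataset_to_records <- function(dataset, species_id = dataset$species_id,
                               start_year = 2002L) {
  rows <- lapply(dataset$series, function(s) {
    T_len <- length(s$observations)
    data.frame(field_id = s$field_id,
               year = start_year + seq_len(T_len) - 1L,
               action = s$actions, species_id = species_id,
               abundance_class = s$observations)
  })
  do.call(rbind, rows)
}

#' Build one species' field series from a records table
#'
#' Groups the table by field, splits each field's surveys at gaps in the
#' year sequence, and keeps runs of at least `min_run` consecutive surveys.
#' Within a run the observation of year t is aligned with the action
#' recorded for year t (the crop of the season culminating in that survey),
#' giving actions indexed 0..T-1 against observations 1..T — so a run of L
#' consecutive surveyed years yields a series of T = L - 1 observations
#' (the first survey has no preceding within-run action and seeds the
#' series implicitly through `p0`). Field-years surveyed for other species
#' but missing for `species_id` are imputed as class 1 (absence) when
#' `impute_absence` is TRUE.
#'
#' @param records a records data frame, see [read_records()].
#' @param species_id the species to extract.
#' @param actions the action set of the resulting dataset (default: all
#'   actions appearing in the table, sorted).
#' @param impute_absence impute class 1 for missing (field, year) pairs.
#' @param min_run minimum consecutive surveyed years per run (default 2).
#' @return A [survey_dataset()]; fields contributing several runs appear as
#'   several series (`<field>#<k>`).
#' @export
records_to_series <- function(records, species_id,
                              actions = sort(unique(records$action)),
                              impute_absence = TRUE, min_run = 2L) {
  surveyed <- unique(records[c("field_id", "year", "action")])
  sp <- records[records$species_id == species_id,
                c("field_id", "year", "abundance_class")]
  tab <- merge(surveyed, sp, by = c("field_id", "year"), all.x = TRUE)
  if (impute_absence) {
    tab$abundance_class[is.na(tab$abundance_class)] <- 1L
  } else {
    tab <- tab[!is.na(tab$abundance_class), , drop = FALSE]
  }
  series <- list()
  for (f in unique(tab$field_id)) {
    rows <- tab[tab$field_id == f, , drop = FALSE]
    rows <- rows[order(rows$year), , drop = FALSE]
    run_id <- cumsum(c(1L, diff(rows$year) != 1L))
    k <- 0L
    for (r in split(seq_len(nrow(rows)), run_id)) {
      if (length(r) < min_run) next
      k <- k + 1L
      id <- if (max(run_id) > 1L) paste0(f, "#", k) else f
      # drop the first survey: it seeds the series through p0; each kept
      # observation pairs with the action of the season it culminates
      series[[length(series) + 1L]] <-
        field_series(id, rows$action[r[-1L]], rows$abundance_class[r[-1L]])
    }
  }
  survey_dataset(series, species_id, actions)
}

#' Read / write the analysis configuration
#'
#' The configuration is a single YAML file mirroring every tunable default:
#' the two class grids and their caps, the Monte-Carlo kernel size `K`, the
#' enumeration cap, the search box (`phi_max`), the random-search and MCMC
#' settings, and the synthetic design. Absent keys fall back to the
#' package defaults.
#'
#' @param path YAML file path.
#' @return For `read_config`, a named list merged over the defaults; for
#'   `write_config`, `path` invisibly.
#' @export
read_config <- function(path) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- default_config()
  cfg[names(user)] <- user
  cfg
}

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_config
#' @export
default_config <- function() {
  sch <- abundance_scheme()
  list(
    emerged_lower = sch$emerged_lower,
    seedbank_lower = sch$seedbank_lower,
    emerged_top_cap = sch$emerged_top_cap,
    seedbank_top_cap = sch$seedbank_top_cap,
    actions = default_actions(),
    K = 30000L,
    backend = "exact",
    production = "poisson",
    phi_max = 200,
    search = list(max_iterations = 50000L, tol = 1e-6, population_size = NULL,
                  polish = TRUE),
    mcmc = list(n_iter = 20000L, burn_in = 5000L, proposal_scales = 0.3,
                thin = 1L),
    cv = list(n_folds = 4L),
    design = list(n_fields = 329L, mean_length = 3.62, sd_length = 1.19,
                  action_freq = c(0.496, 0.102, 0.293, 0.108) / 0.999)
  )
}

#' @rdname read_config
#' @param cfg a configuration list.
#' @return For `config_scheme`, the [abundance_scheme()] the config encodes.
#' @export
config_scheme <- function(cfg) {
  abundance_scheme(cfg$emerged_lower, cfg$seedbank_lower,
                   cfg$emerged_top_cap, cfg$seedbank_top_cap)
}
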