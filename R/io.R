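# Cohort CSV round-tripping and run configuration.

.cohort_cols <- c("patient_id", "start_day", "group", "survival_days",
                  "month_index", "weight_kg", "dose_mg_per_kg", "flag")

#' Write and read a cohort CSV
#'
#' One row per patient-month with the columns `patient_id`, `start_day`,
#' `group`, `survival_days`, `month_index` (0-based), `weight_kg`,
#' `dose_mg_per_kg` and `flag`; off-study months carry empty weight/dose
#' fields. The write/read roundtrip is lossless, including every flag bit.
#'
#' @param cohort An `he_cohort` tibble.
#' @param path CSV file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(as_tibble(cohort)[.cohort_cols], path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @return `read_cohort_csv()` returns an `he_cohort` tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such cohort file: %s", path))
  hdr <- names(suppressWarnings(
    readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                    name_repair = "minimal")))
  if (length(hdr) == 0) abort(sprintf("%s: empty file, expected cohort schema", path))
  extra <- setdiff(hdr, .cohort_cols)
  missing <- setdiff(.cohort_cols, hdr)
  if (length(extra) > 0) {
    abort(sprintf("%s: unknown column(s): %s", path, paste(extra, collapse = ", ")))
  }
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  out <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      start_day = readr::col_integer(),
      group = readr::col_character(),
      survival_days = readr::col_integer(),
      month_index = readr::col_integer(),
      weight_kg = readr::col_double(),
      dose_mg_per_kg = readr::col_double(),
      flag = readr::col_integer()),
    na = "", show_col_types = FALSE))
  pr <- readr::problems(out)
  if (nrow(pr) > 0) {
    abort(sprintf("%s: malformed value at line %d, column %s",
                  path, pr$row[1], pr$col[1]))
  }
  bad <- which(is.na(out$patient_id) | is.na(out$month_index) | is.na(out$flag))
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed row at line %d (missing required field)",
                  path, bad[1] + 1L))
  }
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  class(out) <- c("he_cohort", class(tibble()))
  out
}

#' Write and read an identification curve CSV (`month,count`)
#'
#' @param curve An `identification_curve` tibble.
#' @param path CSV file path.
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(as_tibble(curve)[c("month", "count")], path)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    month = readr::col_integer(), count = readr::col_integer()),
    show_col_types = FALSE)
  class(out) <- c("identification_curve", class(tibble()))
  out
}

# ----------------------------------------------------------- run config ------

.config_defaults <- list(
  n_patients = 1000, p_exceptional = 0.05, mu_std = 8, sigma_std = 1,
  mu_exc = 11, sigma_exc = 1, study_months = 48, start_window_months = 6,
  lambda = 128, depth = 0, max_value = NULL, seed = 1,
  milestones = list(10, "all"),
  paths = list(cohort = "cohort.csv", keys = "keys", counts = "counts.json",
               curve = "curve.csv", timing = "timing.csv",
               exposures = "exposures.csv"))

#' Read and write a run configuration
#'
#' A single declarative YAML file drives a full reproducible run: cohort
#' parameters, requested encryption parameters (`lambda`, `depth`,
#' `max_value`), the master `seed` (wall-clock seeding is never used; stage
#' seeds are derived from the master seed via [split_seed()]), milestone
#' list, and output paths. Omitted fields take the package defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- modifyList(.config_defaults, cfg)
  if (is.null(out$seed)) abort("config must set an explicit integer `seed`")
  structure(out, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Derive per-stage seeds from a master seed
#'
#' Documented splitter: seeds the RNG with the master seed and draws `n`
#' integers below 2^31, one per pipeline stage, so that every stage is
#' independently reproducible from the master seed alone.
#'
#' @param master Master seed (integer).
#' @param n Number of stage seeds.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max, n)
}

#' Run the full pipeline from a configuration
#'
#' simulate -> keygen -> encrypt + count -> decrypt curve -> milestones,
#' entirely determined by the configuration (see [read_run_config()]).
#'
#' @param config A `run_config` (or path to one).
#' @return A list with `cohort`, `study` (an `he_study`), and `milestones`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  seeds <- split_seed(config$seed, 2)
  cohort <- simulate_cohort(
    n_patients = config$n_patients, p_exceptional = config$p_exceptional,
    mu_std = config$mu_std, sigma_std = config$sigma_std,
    mu_exc = config$mu_exc, sigma_exc = config$sigma_exc,
    study_months = config$study_months,
    start_window_months = config$start_window_months, seed = seeds[1])
  params <- derive_params(config$lambda,
                          max_value = config$max_value %||% config$n_patients,
                          mult_depth = config$depth)
  study <- run_study(cohort, params = params, seed = seeds[2])
  ms <- lapply(config$milestones, function(k) {
    m <- suppressWarnings(milestone_months(study$curve, k))
    tibble(milestone = as.character(k), month = m)
  })
  list(cohort = cohort, study = study, milestones = dplyr::bind_rows(ms))
}
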