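# Simulated longitudinal oncology cohort: a two-component survival mixture
# (standard vs exceptional responders), staggered study entry, monthly visit
# records with weight and dose, and per-month 0/1 responder-status flags.

# truncated-normal draws by rejection; exact for sd = 0
.rtnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) abort("degenerate truncation: mean outside bounds")
    return(rep(mean, n))
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Simulate an exceptional-responder cohort
#'
#' Generates a longitudinal cohort in which most patients survive about
#' `mu_std` months while a fraction `p_exceptional` of exceptional responders
#' survives about `mu_exc` months. Each patient gets a uniformly random start
#' day within the enrollment window, an integer survival time drawn from their
#' group's normal distribution (in days, truncated at 1), and monthly weight
#' (kg) and dose (mg/kg) measurements for every month they are alive and on
#' study. Responder-status flags are filled by [compute_flags()].
#'
#' @param n_patients Cohort size (the reference study sizes are 1000 and 5000).
#' @param p_exceptional Fraction of exceptional survivors (default 0.05).
#' @param mu_std,sigma_std Mean and SD of standard survival, months (8, 1).
#' @param mu_exc,sigma_exc Mean and SD of exceptional survival, months (11, 1).
#' @param study_months Length of the study in monthly visits (48).
#' @param start_window_months Enrollment window; start days are uniform over
#'   `[0, start_window_months * days_per_month)` (default 6 months).
#' @param days_per_month Fixed month length in days (30).
#' @param weight_mean,weight_sd,weight_range Monthly body-weight distribution,
#'   kg; normal truncated to `weight_range` (defaults 75, 10, \[40, 150\]).
#' @param dose_mean,dose_sd,dose_range Monthly dose distribution, mg/kg;
#'   normal truncated to `dose_range` (defaults 2.5, 0.5, (0, 6\]).
#' @param seed Optional integer seed; the cohort is then a pure function of
#'   the arguments.
#'
#' @return A tibble of class `he_cohort` with one row per patient per study
#'   month (`n_patients * study_months` rows): `patient_id`, `start_day`,
#'   `group` (`"standard"`/`"exceptional"`), `survival_days`, `month_index`
#'   (0-based from study open), `weight_kg` and `dose_mg_per_kg` (`NA` for
#'   months the patient is not alive and on study), and the 0/1 `flag`
#'   column. Simulation settings are attached as attribute `"params"`.
#' @examples
#' coh <- simulate_cohort(100, seed = 1)
#' dplyr::count(cohort_patients(coh), group)
#' @export
simulate_cohort <- function(n_patients = 1000,
                            p_exceptional = 0.05,
                            mu_std = 8, sigma_std = 1,
                            mu_exc = 11, sigma_exc = 1,
                            study_months = 48,
                            start_window_months = 6,
                            days_per_month = 30,
                            weight_mean = 75, weight_sd = 10,
                            weight_range = c(40, 150),
                            dose_mean = 2.5, dose_sd = 0.5,
                            dose_range = c(0, 6),
                            seed = NULL) {
  if (n_patients < 1) abort("`n_patients` must be positive")
  if (p_exceptional < 0 || p_exceptional > 1) abort("`p_exceptional` must be in [0, 1]")
  if (sigma_std < 0 || sigma_exc < 0 || weight_sd < 0 || dose_sd < 0) {
    abort("standard deviations must be non-negative")
  }
  if (study_months < start_window_months) {
    abort("`study_months` must be at least `start_window_months`")
  }
  if (!is.null(seed)) set.seed(seed)
  params <- list(n_patients = n_patients, p_exceptional = p_exceptional,
                 mu_std = mu_std, sigma_std = sigma_std,
                 mu_exc = mu_exc, sigma_exc = sigma_exc,
                 study_months = study_months,
                 start_window_months = start_window_months,
                 days_per_month = days_per_month,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 weight_range = weight_range,
                 dose_mean = dose_mean, dose_sd = dose_sd,
                 dose_range = dose_range, seed = seed)

  dpm <- days_per_month
  grp <- ifelse(rbinom(n_patients, 1, p_exceptional) == 1, "exceptional", "standard")
  mu <- ifelse(grp == "exceptional", mu_exc, mu_std) * dpm
  sg <- ifelse(grp == "exceptional", sigma_exc, sigma_std) * dpm
  survival_days <- pmax(1L, as.integer(round(rnorm(n_patients, mu, sg))))
  start_day <- as.integer(sample.int(start_window_months * dpm, n_patients,
                                     replace = TRUE) - 1L)

  pts <- tibble(
    patient_id = sprintf("P%05d", seq_len(n_patients)),
    start_day = start_day,
    group = grp,
    survival_days = survival_days
  )

  grid <- tidyr::expand_grid(pts, month_index = 0:(study_months - 1L))
  death_day <- grid$start_day + grid$survival_days
  on_study <- grid$month_index >= grid$start_day %/% dpm &
    grid$month_index <= pmin((death_day - 1L) %/% dpm, study_months - 1L)
  grid$weight_kg <- NA_real_
  grid$dose_mg_per_kg <- NA_real_
  n_on <- sum(on_study)
  # measurements recorded at clinical precision: 0.1 kg, 0.01 mg/kg
  grid$weight_kg[on_study] <- round(.rtnorm(n_on, weight_mean, weight_sd,
                                            weight_range[1], weight_range[2]), 1)
  grid$dose_mg_per_kg[on_study] <- round(.rtnorm(n_on, dose_mean, dose_sd,
                                                 max(dose_range[1], 0.005),
                                                 dose_range[2]), 2)
  out <- compute_flags(structure(grid, params = params))
  class(out) <- c("he_cohort", class(tibble()))
  attr(out, "params") <- params
  out
}

#' Fill per-month responder-status flags
#'
#' A patient in the exceptional group is flagged from the study month in which
#' their unusually long survival is fully observed: the month containing day
#' `start_day + survival_days` (0-based, fixed 30-day months). Flags are 0
#' before that month and 1 from it onward; standard-group patients stay 0.
#'
#' @param cohort An `he_cohort` tibble (flags present or not).
#' @return The cohort with its `flag` column (re)computed.
#' @export
compute_flags <- function(cohort) {
  params <- attr(cohort, "params")
  dpm <- if (!is.null(params)) params$days_per_month else 30
  flag_month <- (cohort$start_day + cohort$survival_days) %/% dpm
  cohort$flag <- as.integer(cohort$group == "exceptional" &
                              cohort$month_index >= flag_month)
  cohort
}

#' One row per patient
#'
#' Collapses a patient-month cohort to its patient-level columns.
#'
#' @param cohort An `he_cohort` tibble.
#' @return A tibble with `patient_id`, `start_day`, `group`, `survival_days`.
#' @export
cohort_patients <- function(cohort) {
  dplyr::distinct(as_tibble(cohort), .data$patient_id, .data$start_day,
                  .data$group, .data$survival_days)
}

#' Histogram of simulated survival times
#'
#' Bins patient survival times (days) into left-closed bins of width
#' `bin_days` from zero. With 5% exceptional survivors the right tail of the
#' distribution is visibly elevated relative to a pure standard-survival fit.
#'
#' @param cohort An `he_cohort` tibble.
#' @param bin_days Bin width in days (default 30).
#' @param by_group If `TRUE`, counts are split by responder group.
#' @return A tibble with `bin_start_days`, `bin_end_days`, optionally `group`,
#'   and `n`; counts sum to the number of patients.
#' @export
survival_histogram <- function(cohort, bin_days = 30, by_group = FALSE) {
  if (bin_days < 1) abort("`bin_days` must be at least 1")
  pts <- cohort_patients(cohort)
  if (nrow(pts) == 0) {
    return(tibble(bin_start_days = integer(), bin_end_days = integer(),
                  n = integer()))
  }
  pts$bin <- pts$survival_days %/% bin_days
  keys <- if (by_group) c("bin", "group") else "bin"
  out <- dplyr::summarise(dplyr::group_by(pts, dplyr::across(dplyr::all_of(keys))),
                          n = dplyr::n(), .groups = "drop")
  out$bin_start_days <- out$bin * bin_days
  out$bin_end_days <- (out$bin + 1L) * bin_days
  dplyr::select(dplyr::arrange(out, .data$bin), dplyr::all_of(
    c("bin_start_days", "bin_end_days", if (by_group) "group", "n")))
}

#' Plaintext identification curve (oracle for the encrypted pipeline)
#'
#' Cumulative count of flagged exceptional responders at each study month,
#' computed directly on the plaintext flags. The encrypted counting pipeline
#' is proven (in the test suite) to decrypt to exactly this curve; large
#' simulation sweeps can therefore use this function in its place.
#'
#' @param cohort An `he_cohort` tibble with flags computed.
#' @return A tibble of class `identification_curve` with `month` (0-based)
#'   and `count`; non-decreasing, final value equals the flagged total.
#' @export
responder_curve <- function(cohort) {
  out <- dplyr::summarise(dplyr::group_by(as_tibble(cohort), month = .data$month_index),
                          count = sum(.data$flag), .groups = "drop")
  out <- dplyr::arrange(out, .data$month)
  class(out) <- c("identification_curve", class(tibble()))
  out
}

#' First study month reaching an identification milestone
#'
#' @param curve An [identification curve][responder_curve] (columns `month`,
#'   `count`, non-decreasing).
#' @param k A count threshold, or `"all"` for the month by which every flagged
#'   responder has been identified.
#' @return The first month with `count >= k` (or reaching the final total for
#'   `"all"`). If the milestone is never reached, returns `NA` with a warning
#'   of class `hecohort_milestone_unreached`.
#' @examples
#' cv <- tibble::tibble(month = 0:4, count = c(0, 0, 2, 2, 3))
#' class(cv) <- c("identification_curve", class(cv))
#' milestone_months(cv, 2)
#' milestone_months(cv, "all")
#' @export
milestone_months <- function(curve, k) {
  stopifnot(all(c("month", "count") %in% names(curve)))
  if (is.unsorted(curve$count)) abort("identification curve must be non-decreasing")
  total <- max(curve$count)
  kk <- if (identical(k, "all")) total else as.numeric(k)
  if (identical(k, "all") && total == 0) {
    warn("milestone unreached: no responder was ever identified",
         class = "hecohort_milestone_unreached")
    return(NA_integer_)
  }
  hit <- which(curve$count >= kk)
  if (length(hit) == 0) {
    warn(sprintf("milestone unreached: count never attains %s", format(kk)),
         class = "hecohort_milestone_unreached")
    return(NA_integer_)
  }
  curve$month[hit[1]]
}
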