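# Shared fixtures and independent oracles for the test suite.

# parameter/key cache so expensive keygens run once per test session
.he_cache <- new.env(parent = emptyenv())
he_fixture <- function(lambda = 128, M = 1000, L = 0, seed = 100) {
  key <- paste(lambda, M, L, seed, sep = "_")
  if (is.null(.he_cache[[key]])) {
    p <- derive_params(lambda, M, L)
    .he_cache[[key]] <- he_keygen(p, seed = seed)
  }
  .he_cache[[key]]
}

# brute-force negacyclic convolution oracle; exact for n * q^2 < 2^53
school_negacyclic <- function(a, b, q) {
  n <- length(a)
  r <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      k <- (i - 1) + (j - 1)
      s <- a[i] * b[j]
      if (k >= n) { k <- k - n; s <- -s }
      r[k + 1] <- r[k + 1] + s
    }
  }
  r %% q
}

# cumulative identification counts computed directly from patient records,
# independent of responder_curve()
oracle_curve <- function(cohort, dpm = 30) {
  pts <- unique(as.data.frame(cohort)[c("patient_id", "start_day", "group",
                                        "survival_days")])
  months <- sort(unique(cohort$month_index))
  flag_month <- ifelse(pts$group == "exceptional",
                       (pts$start_day + pts$survival_days) %/% dpm, Inf)
  vapply(months, function(m) sum(flag_month <= m), numeric(1))
}

# Monte-Carlo oracle for noncentral chi-squared power: sum of squared shifted
# normals with the offsets spread so that sum(delta^2) = ncp
mc_power <- function(w, n, df, alpha, reps = 1e5) {
  crit <- qchisq(1 - alpha, df)
  ncp <- n * w^2
  delta <- sqrt(ncp / df)
  x <- matrix(rnorm(reps * df, mean = delta), nrow = reps)
  mean(rowSums(x^2) > crit)
}

# hand-built patient-month cohort for pipeline unit tests
toy_cohort <- function(start_day, survival_days, group, study_months = 6,
                       weight = NULL, dose = NULL, dpm = 30) {
  np <- length(start_day)
  grid <- expand.grid(pt = seq_len(np), month_index = 0:(study_months - 1))
  grid <- grid[order(grid$pt, grid$month_index), ]
  out <- tibble::tibble(
    patient_id = sprintf("T%03d", grid$pt),
    start_day = as.integer(start_day[grid$pt]),
    group = group[grid$pt],
    survival_days = as.integer(survival_days[grid$pt]),
    month_index = as.integer(grid$month_index))
  death <- out$start_day + out$survival_days
  on_study <- out$month_index >= out$start_day %/% dpm &
    out$month_index <= pmin((death - 1L) %/% dpm, study_months - 1L)
  out$weight_kg <- ifelse(on_study, if (is.null(weight)) 75 else weight[grid$pt], NA_real_)
  out$dose_mg_per_kg <- ifelse(on_study, if (is.null(dose)) 2 else dose[grid$pt], NA_real_)
  out <- compute_flags(out)
  class(out) <- c("he_cohort", class(tibble::tibble()))
  attr(out, "params") <- list(study_months = study_months, days_per_month = dpm,
                              weight_range = c(40, 150), dose_range = c(0, 6),
                              n_patients = np)
  out
}
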