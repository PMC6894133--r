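# The two encrypted analyses: monthly homomorphic counting of exceptional
# responders (the identification curve) and encrypted total drug exposure
# (weight x dose per month, summed). Counting and exposure computations take
# only public material; the secret key appears exactly once, at the final
# decryption of the aggregates.

#' Encrypt the responder-flag matrix
#'
#' Encrypts every patient's 0/1 responder flag at every study month
#' individually under the public key. The result holds ciphertexts only; no
#' plaintext flag is retained.
#'
#' @param cohort An `he_cohort` tibble with flags computed.
#' @param pk An `he_public_key` (or `he_keys` bundle). The plaintext modulus
#'   must exceed the number of patients so that monthly counts cannot wrap.
#' @return An object of class `encrypted_flag_matrix` (dimensions
#'   `n_patients x study_months`).
#' @export
encrypt_flag_matrix <- function(cohort, pk) {
  if (inherits(pk, "he_keys")) pk <- pk$pk
  stopifnot(inherits(pk, "he_public_key"))
  p <- pk$params
  wide <- tidyr::pivot_wider(as_tibble(cohort)[c("patient_id", "month_index", "flag")],
                             names_from = "month_index", values_from = "flag",
                             names_sort = TRUE)
  ids <- wide$patient_id
  fm <- as.matrix(wide[-1])
  storage.mode(fm) <- "integer"
  if (p$t <= nrow(fm)) {
    abort(sprintf(
      "count overflow risk: plaintext modulus t = %d cannot hold counts up to %d patients",
      p$t, nrow(fm)))
  }
  store <- cpp_encrypt_store(fm, pk$p0, pk$p1, p$n, p$q_bits, p$t)
  structure(list(store = store, n_patients = nrow(fm), study_months = ncol(fm),
                 patient_ids = ids, params = p),
            class = "encrypted_flag_matrix")
}

#' @export
print.encrypted_flag_matrix <- function(x, ...) {
  cat(sprintf("<encrypted flag matrix: %d patients x %d months, n = %d>\n",
              x$n_patients, x$study_months, x$params$n))
  invisible(x)
}

# extract one entry as a ciphertext (serialization / determinism checks)
efm_ciphertext <- function(efm, patient, month) {
  stopifnot(inherits(efm, "encrypted_flag_matrix"))
  p <- efm$params
  new_ciphertext(cpp_store_get(efm$store, patient - 1L, month - 1L, p$n, p$q_bits), p)
}

# decrypt every entry (test utility: oracle-equality checks only)
efm_decrypt_all <- function(efm, sk) {
  if (inherits(sk, "he_keys")) sk <- sk$sk
  p <- efm$params
  m <- cpp_store_decrypt(efm$store, sk$s, p$n, p$q_bits, p$t)
  rownames(m) <- efm$patient_ids
  m
}

#' Homomorphic monthly counts of identified responders
#'
#' For each study month, sums the encrypted flags of all patients while the
#' data remain encrypted. Because flags are cumulative (a flag stays 1 once
#' responder status is achieved), each monthly sum is the cumulative
#' identification count. Operates on ciphertexts only; no secret key is in
#' scope.
#'
#' @param efm An [encrypted_flag_matrix()].
#' @return An object of class `encrypted_counts`: one ciphertext per month.
#' @export
count_responders_by_month <- function(efm) {
  stopifnot(inherits(efm, "encrypted_flag_matrix"))
  p <- efm$params
  raw <- cpp_store_col_sums(efm$store, p$n, p$q_bits)
  cts <- lapply(raw, new_ciphertext, params = p)
  structure(list(cts = cts, params = p, months = efm$study_months),
            class = "encrypted_counts")
}

#' @export
print.encrypted_counts <- function(x, ...) {
  cat(sprintf("<encrypted monthly counts: %d months, n = %d>\n",
              x$months, x$params$n))
  invisible(x)
}

#' Decrypt monthly counts into an identification curve
#'
#' The single point in the counting pipeline where the secret key is used.
#'
#' @param counts An [encrypted counts][count_responders_by_month] object.
#' @param sk An `he_secret_key` (or `he_keys` bundle).
#' @return An `identification_curve` tibble (`month`, `count`).
#' @export
decrypt_counts <- function(counts, sk) {
  if (inherits(sk, "he_keys")) sk <- sk$sk
  stopifnot(inherits(counts, "encrypted_counts"))
  vals <- vapply(counts$cts, function(ct) he_decrypt(sk, ct), numeric(1))
  out <- tibble(month = seq_along(vals) - 1L, count = as.integer(vals))
  class(out) <- c("identification_curve", class(tibble()))
  out
}

# ------------------------------------------------------------- exposure ------

# fixed-point convention: weight in whole kg, dose in tenths of mg/kg,
# exposure totals in 0.1 mg units
.fixed_point <- function(rows) {
  ok <- !is.na(rows$weight_kg) & !is.na(rows$dose_mg_per_kg)
  list(w = as.integer(round(rows$weight_kg[ok])),
       d = as.integer(round(10 * rows$dose_mg_per_kg[ok])))
}

#' Largest plausible total exposure, in fixed-point units
#'
#' Worst-case bound `study_months * max_weight * max_dose` under the fixed
#' point convention (weight in kg, dose in tenths of mg/kg), used to size the
#' plaintext modulus for the exposure analysis.
#'
#' @param cohort An `he_cohort` tibble.
#' @return Integer bound in 0.1 mg units.
#' @export
exposure_bound <- function(cohort) {
  p <- attr(cohort, "params")
  if (!is.null(p)) {
    ceiling(p$study_months * ceiling(p$weight_range[2]) *
              ceiling(10 * p$dose_range[2]))
  } else {
    rows <- as_tibble(cohort)
    months <- length(unique(rows$month_index))
    ceiling(months * max(round(rows$weight_kg), na.rm = TRUE) *
              max(round(10 * rows$dose_mg_per_kg), na.rm = TRUE))
  }
}

#' Encrypted total drug exposure per patient
#'
#' For each on-study month, encrypts the patient's weight (kg) and dose
#' (tenths of mg/kg) separately, multiplies the two ciphertexts
#' homomorphically (tensor + relinearization), and accumulates the monthly
#' products with homomorphic addition. A single decryption at the end yields
#' the total exposure in 0.1 mg units, exactly equal to the plaintext
#' fixed-point computation.
#'
#' @param cohort An `he_cohort` tibble.
#' @param keys An `he_keys` bundle whose parameters support one multiplication
#'   and whose `max_value` is at least [exposure_bound()] of the cohort;
#'   otherwise an overflow error is raised at setup.
#' @param patient_ids Optional character vector restricting the computation
#'   to a subset of patients.
#' @return A tibble: `patient_id`, `months_on_study`, `total_exposure_units`
#'   (0.1 mg) and `total_exposure_mg`.
#' @export
encrypted_total_exposure <- function(cohort, keys, patient_ids = NULL) {
  stopifnot(inherits(keys, "he_keys"))
  p <- keys$params
  bound <- exposure_bound(cohort)
  if (p$depth < 1) abort("exposure needs parameters with mult_depth >= 1")
  if (p$max_value < bound) {
    abort(sprintf(
      "overflow risk at setup: parameters hold values up to %d but total exposure can reach %d fixed-point units",
      p$max_value, bound))
  }
  rows <- as_tibble(cohort)
  ids <- patient_ids %||% unique(rows$patient_id)
  res <- purrr::map(ids, function(id) {
    pr <- rows[rows$patient_id == id, ]
    fx <- .fixed_point(pr)
    if (length(fx$w) == 0) {
      return(tibble(patient_id = id, months_on_study = 0L,
                    total_exposure_units = 0))
    }
    ct <- new_ciphertext(
      cpp_exposure_ct(fx$w, fx$d, keys$pk$p0, keys$pk$p1,
                      keys$rlk$b, keys$rlk$a, p$n, p$q_bits, p$t,
                      keys$rlk$w_bits), p)
    tibble(patient_id = id, months_on_study = length(fx$w),
           total_exposure_units = he_decrypt(keys$sk, ct))
  })
  out <- dplyr::bind_rows(res)
  out$total_exposure_mg <- out$total_exposure_units / 10
  out
}

#' Plaintext total exposure (oracle for the encrypted computation)
#'
#' @inheritParams encrypted_total_exposure
#' @return Same shape as [encrypted_total_exposure()], computed directly on
#'   the plaintext records under the identical fixed-point convention.
#' @export
plaintext_total_exposure <- function(cohort, patient_ids = NULL) {
  rows <- as_tibble(cohort)
  ids <- patient_ids %||% unique(rows$patient_id)
  res <- purrr::map(ids, function(id) {
    fx <- .fixed_point(rows[rows$patient_id == id, ])
    tibble(patient_id = id, months_on_study = length(fx$w),
           total_exposure_units = sum(as.numeric(fx$w) * fx$d))
  })
  out <- dplyr::bind_rows(res)
  out$total_exposure_mg <- out$total_exposure_units / 10
  out
}

# ------------------------------------------------------------- run_study -----

#' Run the encrypted identification study end to end
#'
#' Generates keys, encrypts all responder flags, counts identified
#' responders month by month under encryption, and decrypts only the monthly
#' aggregates. Wall-clock time per stage is recorded; the study is feasible
#' when the computation time per month is far below one month, which is
#' logged rather than asserted.
#'
#' @param cohort An `he_cohort` tibble with flags computed.
#' @param params Optional [he_params][derive_params]; defaults to
#'   `derive_params(lambda, max_value = n_patients, mult_depth = 0)`.
#' @param lambda Security level used when `params` is `NULL`.
#' @param seed Optional seed for key generation and encryption.
#' @return An object of class `he_study`: `curve` (identification curve),
#'   `timing` (tibble of stage durations in seconds), `params`, and
#'   `n_patients`.
#' @export
run_study <- function(cohort, params = NULL, lambda = 128, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  npat <- nrow(cohort_patients(cohort))
  params <- params %||% derive_params(lambda, max_value = npat, mult_depth = 0)
  tic <- function(expr) system.time(expr)[["elapsed"]]
  keys <- NULL; efm <- NULL; counts <- NULL; curve <- NULL
  t_key <- tic(keys <- he_keygen(params))
  t_enc <- tic(efm <- encrypt_flag_matrix(cohort, keys$pk))
  t_add <- tic(counts <- count_responders_by_month(efm))
  t_dec <- tic(curve <- decrypt_counts(counts, keys$sk))
  timing <- tibble(
    stage = c("keygen", "encrypt", "add", "decrypt"),
    seconds = c(t_key, t_enc, t_add, t_dec))
  structure(list(curve = curve, timing = timing, params = params,
                 n_patients = npat),
            class = "he_study")
}

#' @export
print.he_study <- function(x, ...) {
  cat(sprintf("<encrypted identification study: %d patients, n = %d, lambda = %d>\n",
              x$n_patients, x$params$n, x$params$lambda))
  print(glance(x))
  invisible(x)
}

# --------------------------------------------------------- timing harness ----

#' Timing harness for the encrypted challenges
#'
#' Measures wall-clock time of the encrypted stages under the reference
#' configurations. `task = "count"` mirrors the identification challenge (per
#' cohort size: encrypt a 0/1 vector for one variable, homomorphically add
#' across all patients, decrypt the total) and includes the
#' hundred-variables-per-analysis extrapolation column (100 x the addition
#' time). `task = "exposure"` mirrors the exposure challenge for a single
#' patient (encrypt all monthly values, multiply weight by dose each month,
#' add, decrypt) with an estimated total for 5000 patients. Durations are
#' hardware-dependent diagnostics, never assertions; the defaults reproduce
#' the reference study conditions and take a long time on large rings.
#'
#' @param sizes Cohort sizes for the counting task (reference: 1000, 5000).
#' @param configs Data frame of (`lambda`, `depth`) configurations
#'   (reference: (128, 8), (256, 8), (256, 16)).
#' @param task `"count"` or `"exposure"`.
#' @param months Months per patient for the exposure task (48).
#' @param max_value Plaintext bound used to derive each parameter set; for
#'   counting it must exceed the largest cohort size.
#' @param seed Optional seed.
#' @return A tibble shaped like the reference timing tables.
#' @export
timing_harness <- function(sizes = c(1000, 5000),
                           configs = data.frame(lambda = c(128, 256, 256),
                                                depth = c(8, 8, 16)),
                           task = c("count", "exposure"),
                           months = 48, max_value = 1000, seed = NULL) {
  task <- match.arg(task)
  if (!is.null(seed)) set.seed(seed)
  tic <- function(expr) system.time(expr)[["elapsed"]]
  rows <- list()
  for (ci in seq_len(nrow(configs))) {
    lam <- configs$lambda[ci]; dep <- configs$depth[ci]
    if (task == "count") {
      params <- derive_params(lam, max_value = max(max_value, max(sizes)),
                              mult_depth = dep)
      keys <- he_keygen(params)
      for (sz in sizes) {
        flags <- rbinom(sz, 1, 0.05)
        cts <- NULL; total <- NULL; val <- NULL
        t_enc <- tic(cts <- lapply(flags, function(f) he_encrypt(keys$pk, f)))
        t_add <- tic(total <- purrr::reduce(cts, he_add))
        t_dec <- tic(val <- he_decrypt(keys$sk, total))
        stopifnot(val == sum(flags))
        rows[[length(rows) + 1]] <- tibble(
          n_patients = sz, lambda = lam, depth = dep,
          encrypt_s = t_enc, add_s = t_add, add_x100_s = 100 * t_add,
          decrypt_s = t_dec)
      }
    } else {
      params <- derive_params(lam, max_value = max(max_value, months * 150 * 60),
                              mult_depth = max(dep, 1))
      keys <- he_keygen(params)
      w <- as.integer(round(.rtnorm(months, 75, 10, 40, 150)))
      d <- as.integer(round(10 * .rtnorm(months, 2.5, 0.5, 1e-9, 6)))
      cw <- NULL; cd <- NULL; prods <- NULL; total <- NULL; val <- NULL
      t_enc <- tic({
        cw <- lapply(w, function(v) he_encrypt(keys$pk, v))
        cd <- lapply(d, function(v) he_encrypt(keys$pk, v))
      })
      t_mul <- tic(prods <- purrr::map2(cw, cd, he_mult, rlk = keys$rlk))
      t_addp <- tic(total <- purrr::reduce(prods, he_add))
      t_dec <- tic(val <- he_decrypt(keys$sk, total))
      stopifnot(val == sum(as.numeric(w) * d))
      tot <- t_enc + t_mul + t_addp + t_dec
      rows[[length(rows) + 1]] <- tibble(
        lambda = lam, depth = dep, encrypt_s = t_enc, multiply_s = t_mul,
        add_s = t_addp, decrypt_s = t_dec, total_s = tot,
        est_5000_patients_h = 5000 * tot / 3600)
    }
  }
  dplyr::bind_rows(rows)
}
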