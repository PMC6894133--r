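# Versioned JSON envelopes for keys and ciphertexts. Coefficients are stored
# as base64 little-endian fixed-width 32-bit limb arrays, so every integer is
# serialized exactly at arbitrary precision.

.limbs_to_b64 <- function(m) {
  v <- as.vector(m)
  bytes <- as.raw(rbind(v %% 256, (v %/% 256) %% 256,
                        (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
  jsonlite::base64_enc(bytes)
}

.b64_to_limbs <- function(s, n, q_bits) {
  lq <- (q_bits + 31) %/% 32
  bytes <- as.numeric(jsonlite::base64_dec(s))
  stopifnot(length(bytes) == 4 * lq * n)
  b <- matrix(bytes, nrow = 4)
  matrix(b[1, ] + 256 * b[2, ] + 65536 * b[3, ] + 16777216 * b[4, ],
         nrow = lq, ncol = n)
}

.params_envelope <- function(p) {
  list(n = p$n, q_bits = p$q_bits, q = p$q, t = p$t, sigma = p$sigma,
       w_base = p$w_base, lambda = p$lambda, depth = p$depth,
       max_value = p$max_value)
}

.params_from_envelope <- function(e) {
  new_he_params(n = e$n, q_bits = e$q_bits, t = e$t, lambda = e$lambda,
                depth = e$depth, max_value = e$max_value)
}

.envelope <- function(kind, params, payload) {
  list(version = 1L, scheme = "FV", kind = kind,
       params = .params_envelope(params), payload = payload)
}

.read_envelope <- function(path, kind) {
  e <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(e$scheme, "FV") || !identical(e$kind, kind)) {
    abort(sprintf("%s is not an FV %s envelope", path, kind))
  }
  e
}

#' Write and read FV keys
#'
#' Serializes a key set to a directory as three JSON envelopes
#' (`secret_key.json`, `public_key.json`, `relin_key.json`). Reading with
#' `which = "public"` loads only the material needed for encryption and
#' homomorphic computation, never touching the secret key file.
#'
#' @param keys An `he_keys` bundle.
#' @param dir Directory to write into (created if needed).
#' @return `write_he_keys()` returns `dir` invisibly; `read_he_keys()`
#'   returns an `he_keys` bundle (with `sk = NULL` for `which = "public"`).
#' @export
write_he_keys <- function(keys, dir) {
  stopifnot(inherits(keys, "he_keys"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- keys$params
  jsonlite::write_json(
    .envelope("secret_key", p, list(s = .limbs_to_b64(keys$sk$s))),
    file.path(dir, "secret_key.json"), auto_unbox = TRUE)
  jsonlite::write_json(
    .envelope("public_key", p, list(p0 = .limbs_to_b64(keys$pk$p0),
                                    p1 = .limbs_to_b64(keys$pk$p1))),
    file.path(dir, "public_key.json"), auto_unbox = TRUE)
  jsonlite::write_json(
    .envelope("relin_key", p,
              list(w_bits = keys$rlk$w_bits,
                   b = lapply(keys$rlk$b, .limbs_to_b64),
                   a = lapply(keys$rlk$a, .limbs_to_b64))),
    file.path(dir, "relin_key.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_he_keys
#' @param which `"all"` (default) or `"public"` (public + relin keys only).
#' @export
read_he_keys <- function(dir, which = c("all", "public")) {
  which <- match.arg(which)
  pub <- .read_envelope(file.path(dir, "public_key.json"), "public_key")
  p <- .params_from_envelope(pub$params)
  pk <- structure(list(p0 = .b64_to_limbs(pub$payload$p0, p$n, p$q_bits),
                       p1 = .b64_to_limbs(pub$payload$p1, p$n, p$q_bits),
                       params = p), class = "he_public_key")
  rl <- .read_envelope(file.path(dir, "relin_key.json"), "relin_key")
  rlk <- structure(list(b = lapply(rl$payload$b, .b64_to_limbs, n = p$n, q_bits = p$q_bits),
                        a = lapply(rl$payload$a, .b64_to_limbs, n = p$n, q_bits = p$q_bits),
                        w_bits = rl$payload$w_bits, params = p),
                   class = "he_relin_key")
  sk <- NULL
  if (which == "all") {
    se <- .read_envelope(file.path(dir, "secret_key.json"), "secret_key")
    sk <- structure(list(s = .b64_to_limbs(se$payload$s, p$n, p$q_bits),
                         params = p), class = "he_secret_key")
  }
  structure(list(sk = sk, pk = pk, rlk = rlk, params = p), class = "he_keys")
}

#' Write and read a ciphertext
#'
#' Single-ciphertext JSON envelope; the serialize/deserialize roundtrip is
#' exact (bit-identical limbs).
#'
#' @param ct An `he_ciphertext`.
#' @param path File path.
#' @export
write_ciphertext <- function(ct, path) {
  stopifnot(inherits(ct, "he_ciphertext"))
  jsonlite::write_json(
    .envelope("ciphertext", ct$params,
              list(parts = lapply(ct$parts, .limbs_to_b64))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ciphertext
#' @export
read_ciphertext <- function(path) {
  e <- .read_envelope(path, "ciphertext")
  p <- .params_from_envelope(e$params)
  new_ciphertext(lapply(e$payload$parts, .b64_to_limbs, n = p$n, q_bits = p$q_bits), p)
}

# encrypted monthly counts: one envelope holding all months
write_encrypted_counts <- function(counts, path) {
  stopifnot(inherits(counts, "encrypted_counts"))
  jsonlite::write_json(
    .envelope("encrypted_counts", counts$params,
              list(months = counts$months,
                   cts = lapply(counts$cts, function(ct)
                     lapply(ct$parts, .limbs_to_b64)))),
    path, auto_unbox = TRUE)
  invisible(path)
}

read_encrypted_counts <- function(path) {
  e <- .read_envelope(path, "encrypted_counts")
  p <- .params_from_envelope(e$params)
  cts <- lapply(e$payload$cts, function(parts)
    new_ciphertext(lapply(parts, .b64_to_limbs, n = p$n, q_bits = p$q_bits), p))
  structure(list(cts = cts, params = p, months = e$payload$months),
            class = "encrypted_counts")
}
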