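# Homomorphic operations on ciphertexts, and the underlying ring arithmetic.

new_ciphertext <- function(parts, params) {
  structure(list(parts = parts, params = params), class = "he_ciphertext")
}

#' Encrypt an integer under an FV public key
#'
#' Produces a fresh size-2 ciphertext
#' `(Delta * m + p0 * u + e1, p1 * u + e2) mod q` with a ternary ephemeral
#' `u` and centered-binomial errors. Two encryptions of the same value differ
#' (semantic security) but decrypt identically.
#'
#' @param pk An `he_public_key` (or an `he_keys` bundle).
#' @param m Integer payload with `abs(m) <= max_value` of the parameter set.
#' @return An `he_ciphertext` of size 2.
#' @export
he_encrypt <- function(pk, m) {
  if (inherits(pk, "he_keys")) pk <- pk$pk
  stopifnot(inherits(pk, "he_public_key"))
  p <- pk$params
  if (length(m) != 1 || is.na(m) || abs(m) > p$max_value) {
    abort(sprintf("payload out of range: |m| must be <= %d", p$max_value))
  }
  parts <- cpp_encrypt(pk$p0, pk$p1, p$n, p$q_bits, p$t, m)
  new_ciphertext(parts, p)
}

#' Decrypt an FV ciphertext
#'
#' Computes `round((t/q) * [c0 + c1 s (+ c2 s^2)]_q)` centered mod `t`.
#' Size-3 ciphertexts (products before relinearization) are decrypted with
#' `s` and `s^2`. If the accumulated noise has exceeded the decryption
#' threshold the returned value is silently wrong; use [he_checked_decrypt()]
#' in tests to detect that condition.
#'
#' @param sk An `he_secret_key` (or an `he_keys` bundle).
#' @param ct An `he_ciphertext`.
#' @return The decrypted integer.
#' @export
he_decrypt <- function(sk, ct) {
  if (inherits(sk, "he_keys")) sk <- sk$sk
  stopifnot(inherits(sk, "he_secret_key"), inherits(ct, "he_ciphertext"))
  .check_params_match(sk$params, ct$params)
  p <- ct$params
  cpp_decrypt(ct$parts, sk$s, p$n, p$q_bits, p$t)$value
}

#' Checked decryption (known-plaintext noise audit)
#'
#' Test utility only: decrypts and raises a "noise exhausted" error when the
#' result does not match the expected plaintext. It is deliberately separate
#' from the analysis path, which never sees plaintexts.
#'
#' @inheritParams he_decrypt
#' @param expected The plaintext the ciphertext should decrypt to.
#' @return The decrypted value, invisibly, when it matches.
#' @export
he_checked_decrypt <- function(sk, ct, expected) {
  got <- he_decrypt(sk, ct)
  if (got != expected) {
    abort(sprintf("noise exhausted: decrypted %d, expected %d", got, expected),
          class = "hecohort_noise_exhausted")
  }
  invisible(got)
}

#' Remaining noise budget of a ciphertext, in bits
#'
#' Returns `log2(q / (2 t |noise|))` clipped at zero, where the noise is the
#' decryption residual `[c0 + c1 s (+ c2 s^2)]_q - Delta * m`. Requires the
#' secret key; it is a testing and diagnostic utility, never part of the
#' encrypted analysis path.
#'
#' @inheritParams he_decrypt
#' @return Non-negative number of bits of budget left.
#' @export
noise_budget <- function(sk, ct) {
  if (inherits(sk, "he_keys")) sk <- sk$sk
  stopifnot(inherits(sk, "he_secret_key"), inherits(ct, "he_ciphertext"))
  p <- ct$params
  nl <- cpp_decrypt(ct$parts, sk$s, p$n, p$q_bits, p$t)$noise_log2
  max(0, p$q_bits - 1 - log2(p$t) - max(nl, 0))
}

#' Homomorphic addition
#'
#' Component-wise sum mod q; decrypts to `m1 + m2` centered mod `t`. A size-2
#' ciphertext is padded with a zero part when added to a size-3 one. Noise
#' grows additively, much more slowly than under multiplication.
#'
#' @param ct1,ct2 `he_ciphertext` objects under the same parameters.
#' @return An `he_ciphertext`.
#' @export
he_add <- function(ct1, ct2) {
  stopifnot(inherits(ct1, "he_ciphertext"), inherits(ct2, "he_ciphertext"))
  .check_params_match(ct1$params, ct2$params)
  p <- ct1$params
  new_ciphertext(cpp_add(ct1$parts, ct2$parts, p$n, p$q_bits), p)
}

#' Homomorphic multiplication
#'
#' Tensor product of two size-2 ciphertexts with `t/q` scaling and rounding
#' (a size-3 intermediate), followed by relinearization back to size 2 using
#' the evaluation key. Decrypts to `m1 * m2` centered mod `t`.
#'
#' @inheritParams he_add
#' @param rlk An `he_relin_key` (or an `he_keys` bundle).
#' @return A size-2 `he_ciphertext`.
#' @export
he_mult <- function(ct1, ct2, rlk) {
  if (inherits(rlk, "he_keys")) rlk <- rlk$rlk
  stopifnot(inherits(rlk, "he_relin_key"))
  he_relinearize(he_mult_norelin(ct1, ct2), rlk)
}

#' @rdname he_mult
#' @description `he_mult_norelin()` returns the size-3 product without
#'   relinearizing (no evaluation key needed); `he_relinearize()` reduces a
#'   size-3 ciphertext back to size 2, preserving its decryption.
#' @export
he_mult_norelin <- function(ct1, ct2) {
  stopifnot(inherits(ct1, "he_ciphertext"), inherits(ct2, "he_ciphertext"))
  .check_params_match(ct1$params, ct2$params)
  if (length(ct1$parts) != 2 || length(ct2$parts) != 2) {
    abort("multiplication operands must be size-2 ciphertexts (relinearize first)")
  }
  p <- ct1$params
  new_ciphertext(cpp_tensor(ct1$parts, ct2$parts, p$n, p$q_bits, p$t), p)
}

#' @rdname he_mult
#' @param ct A size-3 `he_ciphertext`.
#' @export
he_relinearize <- function(ct, rlk) {
  if (inherits(rlk, "he_keys")) rlk <- rlk$rlk
  stopifnot(inherits(ct, "he_ciphertext"), inherits(rlk, "he_relin_key"))
  .check_params_match(ct$params, rlk$params)
  if (length(ct$parts) != 3) abort("relinearization expects a size-3 ciphertext")
  p <- ct$params
  new_ciphertext(cpp_relin(ct$parts, rlk$b, rlk$a, p$n, p$q_bits, rlk$w_bits), p)
}

#' @export
print.he_ciphertext <- function(x, ...) {
  cat(sprintf("<FV ciphertext, size %d, n = %d, log2(q) = %d>\n",
              length(x$parts), x$params$n, x$params$q_bits))
  invisible(x)
}

# ----------------------------------------------------------- ring elements ---

#' Ring elements of Z_q[X]/(X^n + 1)
#'
#' Low-level access to the polynomial ring underlying the scheme. `ring_element()`
#' builds an element from integer coefficients (recycled with zeros to length
#' `n`, reduced mod `q = 2^q_bits`), `ring_multiply()` is the negacyclic
#' product (`X^n = -1`), `ring_add()` the coefficient-wise sum, and
#' `ring_coeffs()` recovers centered coefficients as doubles (exact whenever
#' the centered magnitudes stay below 2^53).
#'
#' @param coeffs Numeric coefficients (may be negative; `|coeffs| < 2^53`).
#' @param n Ring dimension (power of two).
#' @param q_bits log2 of the modulus.
#' @return `ring_element()` returns an object of class `ring_element`.
#' @examples
#' a <- ring_element(c(1, 1), n = 2, q_bits = 20)
#' b <- ring_element(c(1, -1), n = 2, q_bits = 20)
#' ring_coeffs(ring_multiply(a, b)) # (1+X)(1-X) = 2 since X^2 = -1
#' @export
ring_element <- function(coeffs, n, q_bits) {
  if (bitwAnd(n, n - 1) != 0 || n < 2) abort("`n` must be a power of two >= 2")
  if (length(coeffs) > n) abort("more coefficients than ring dimension")
  coeffs <- c(coeffs, rep(0, n - length(coeffs)))
  structure(list(limbs = cpp_poly_from_ints(as.numeric(coeffs), n, q_bits),
                 n = n, q_bits = q_bits),
            class = "ring_element")
}

.check_ring_match <- function(a, b) {
  if (a$n != b$n || a$q_bits != b$q_bits) {
    abort("ring elements live in different rings (n or q mismatch)")
  }
}

#' @rdname ring_element
#' @param a,b `ring_element` objects over the same ring.
#' @export
ring_multiply <- function(a, b) {
  stopifnot(inherits(a, "ring_element"), inherits(b, "ring_element"))
  .check_ring_match(a, b)
  structure(list(limbs = cpp_ring_mult(a$limbs, b$limbs, a$n, a$q_bits),
                 n = a$n, q_bits = a$q_bits), class = "ring_element")
}

#' @rdname ring_element
#' @export
ring_add <- function(a, b) {
  stopifnot(inherits(a, "ring_element"), inherits(b, "ring_element"))
  .check_ring_match(a, b)
  structure(list(limbs = cpp_ring_add(a$limbs, b$limbs, a$n, a$q_bits),
                 n = a$n, q_bits = a$q_bits), class = "ring_element")
}

#' @rdname ring_element
#' @param x A `ring_element`.
#' @export
ring_coeffs <- function(x) {
  stopifnot(inherits(x, "ring_element"))
  cpp_poly_centered(x$limbs, x$n, x$q_bits)
}

#' @export
print.ring_element <- function(x, ...) {
  cat(sprintf("<ring element, n = %d, log2(q) = %d>\n", x$n, x$q_bits))
  invisible(x)
}
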