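# Parameter selection for the FV scheme.
#
# The ciphertext modulus is always q = 2^B. B is bounded above, per ring
# dimension and security level, by the published homomorphic-encryption
# security standard (ternary secret, classical attacks). derive_params() scans
# ring dimensions upward until a calibrated noise-growth estimate for the
# requested multiplicative depth fits under the bound.

.sec_table <- list(
  "128" = c("1024" = 27, "2048" = 54, "4096" = 109, "8192" = 218,
            "16384" = 438, "32768" = 881),
  "256" = c("1024" = 13, "2048" = 29, "4096" = 58, "8192" = 118,
            "16384" = 237, "32768" = 476)
)

# Empirically calibrated log2 noise-growth model for sequential multiplication
# chains (each step multiplies by a fresh ciphertext). Constants were fitted to
# measured noise trajectories and carry an 8-bit correctness margin.
.required_bits <- function(n, t, depth, cap) {
  v <- log2(21 * (1 + 4 * sqrt(n)))   # fresh noise bound, centered-binomial errors
  ell <- ceiling(cap / 8)
  relin_floor <- log2(ell) + 8 + 4.4 + 0.5 * log2(n) + 2.2
  if (depth > 0) {
    for (i in seq_len(depth)) {
      v <- max(v + log2(t) + 0.5 * log2(n) + 6.5, relin_floor)
    }
  }
  ceiling(v + log2(2 * t)) + 8
}

#' Derive FV encryption parameters
#'
#' Selects the smallest ring dimension in the built-in security table whose
#' modulus budget accommodates the requested multiplicative depth at a
#' plaintext modulus large enough to hold signed values up to `max_value`.
#' The plaintext modulus is `t = 2 * max_value + 1` and the ciphertext modulus
#' is `q = 2^q_bits` with `q_bits` never exceeding the security-standard bound
#' for (`security_bits`, `n`).
#'
#' @param security_bits Security level lambda; 128 or 256.
#' @param max_value Largest plaintext magnitude the scheme must represent
#'   exactly (default 1000). Homomorphic results must also stay within this
#'   bound, so size it for the final aggregate, not the inputs.
#' @param mult_depth Number of consecutive homomorphic multiplications the
#'   parameters must support (default 0, additions only).
#' @param verify If `TRUE`, run an empirical depth certificate: encrypt 2 and
#'   multiply by fresh encryptions of 1 `mult_depth` times, checking that the
#'   chain still decrypts correctly. Costly for large rings; the same
#'   certificate is exercised by the package test suite.
#'
#' @return An object of class `he_params`: ring dimension `n`, modulus bits
#'   `q_bits` (with `q` as a decimal string), plaintext modulus `t`, error
#'   standard deviation `sigma`, relinearization base `w_base`, security level
#'   `lambda`, supported depth `depth`, and `max_value`.
#' @examples
#' derive_params(128, max_value = 1000, mult_depth = 1)
#' @export
derive_params <- function(security_bits = 128, max_value = 1000, mult_depth = 0,
                          verify = FALSE) {
  if (!security_bits %in% c(128, 256)) {
    abort("`security_bits` must be 128 or 256")
  }
  if (max_value < 1) abort("`max_value` must be at least 1")
  if (mult_depth < 0) abort("`mult_depth` must be non-negative")
  t <- 2 * max_value + 1
  if (t >= 2^31) {
    abort("parameters unattainable: max_value too large for the plaintext modulus (t must stay below 2^31)")
  }
  tab <- .sec_table[[as.character(security_bits)]]
  for (nm in names(tab)) {
    n <- as.numeric(nm)
    cap <- tab[[nm]]
    hard <- .required_bits(n, t, mult_depth, cap)
    if (hard <= cap) {
      p <- new_he_params(n = n, q_bits = min(cap, hard + 24), t = t,
                         lambda = security_bits, depth = mult_depth,
                         max_value = max_value)
      if (verify) .verify_depth(p)
      return(p)
    }
  }
  abort(sprintf(paste0(
    "parameters unattainable: depth %d at max_value %d needs more modulus ",
    "than the security table allows at lambda = %d (binding constraint: ",
    "largest ring n = 32768 caps log2(q) at %d bits)"),
    mult_depth, max_value, security_bits, tab[["32768"]]))
}

new_he_params <- function(n, q_bits, t, lambda, depth, max_value) {
  structure(
    list(n = as.integer(n), q_bits = as.integer(q_bits),
         q = cpp_pow2_dec(as.integer(q_bits)), t = as.numeric(t),
         sigma = 3.2, w_base = 256L, lambda = as.integer(lambda),
         depth = as.integer(depth), max_value = as.numeric(max_value)),
    class = "he_params")
}

.w_bits <- function(params) as.integer(round(log2(params$w_base)))

.verify_depth <- function(params) {
  keys <- he_keygen(params)
  ct <- he_encrypt(keys$pk, 2)
  d <- max(1, params$depth)
  for (i in seq_len(d)) {
    ct <- he_mult(ct, he_encrypt(keys$pk, 1), keys$rlk)
  }
  if (he_decrypt(keys$sk, ct) != 2) {
    abort("empirical depth certificate failed for derived parameters")
  }
  invisible(params)
}

.check_params_match <- function(p1, p2) {
  if (p1$n != p2$n || p1$q_bits != p2$q_bits || p1$t != p2$t) {
    abort("incompatible parameter sets: ring dimension, modulus and plaintext modulus must match")
  }
  invisible(TRUE)
}

#' @export
print.he_params <- function(x, ...) {
  cat("<FV parameters>\n")
  cat(sprintf("  ring dimension n : %d\n", x$n))
  cat(sprintf("  log2(q)          : %d\n", x$q_bits))
  cat(sprintf("  plaintext mod t  : %d (max |value| %d)\n", x$t, x$max_value))
  cat(sprintf("  security lambda  : %d bits\n", x$lambda))
  cat(sprintf("  mult depth       : %d\n", x$depth))
  cat(sprintf("  error sigma      : %.1f, relin base 2^%d\n", x$sigma, .w_bits(x)))
  invisible(x)
}

#' @rdname derive_params
#' @param x An `he_params` object.
#' @param ... Unused.
#' @export
glance.he_params <- function(x, ...) {
  tibble(n = x$n, q_bits = x$q_bits, t = x$t, lambda = x$lambda,
         depth = x$depth, max_value = x$max_value, sigma = x$sigma,
         w_base = x$w_base)
}
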