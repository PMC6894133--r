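# Key generation and key objects.

#' Generate an FV key set
#'
#' Draws a ternary secret key, a public key pair `(p0, p1)` with
#' `p0 = -(p1 * s + e)` mod q, and a base-`w` relinearization key. All
#' randomness comes from R's RNG, so keys are reproducible with
#' [set.seed()] or the `seed` argument.
#'
#' @param params An [he_params][derive_params] object.
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called
#'   first so the key set is a pure function of (`params`, `seed`).
#' @return An object of class `he_keys` with elements `sk`, `pk`, `rlk`
#'   (classes `he_secret_key`, `he_public_key`, `he_relin_key`) and `params`.
#'   Each component also carries `params` so it can be used on its own.
#' @examples
#' p <- derive_params(128, 10, 0)
#' k <- he_keygen(p, seed = 1)
#' he_decrypt(k$sk, he_encrypt(k$pk, 7))
#' @export
he_keygen <- function(params, seed = NULL) {
  stopifnot(inherits(params, "he_params"))
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_keygen(params$n, params$q_bits, params$t, .w_bits(params))
  sk <- structure(list(s = raw$s, params = params), class = "he_secret_key")
  pk <- structure(list(p0 = raw$p0, p1 = raw$p1, params = params),
                  class = "he_public_key")
  rlk <- structure(list(b = raw$rlk_b, a = raw$rlk_a,
                        w_bits = .w_bits(params), params = params),
                   class = "he_relin_key")
  structure(list(sk = sk, pk = pk, rlk = rlk, params = params),
            class = "he_keys")
}

#' @export
print.he_keys <- function(x, ...) {
  cat("<FV key set>\n")
  print(x$params)
  invisible(x)
}

#' @export
print.he_secret_key <- function(x, ...) {
  cat(sprintf("<FV secret key, n = %d (ternary)>\n", x$params$n))
  invisible(x)
}

#' @export
print.he_public_key <- function(x, ...) {
  cat(sprintf("<FV public key, n = %d, log2(q) = %d>\n",
              x$params$n, x$params$q_bits))
  invisible(x)
}

#' @export
print.he_relin_key <- function(x, ...) {
  cat(sprintf("<FV relinearization key, %d components, base 2^%d>\n",
              length(x$b), x$w_bits))
  invisible(x)
}
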