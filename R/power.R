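# Chi-squared power analysis via the noncentral chi-squared distribution,
# used to size the cohorts. The upper tail of the noncentral distribution is
# computed from first principles as a Poisson-weighted mixture of central
# chi-squared tails; the test suite cross-checks it against both R's ncp
# machinery and a Monte-Carlo oracle.

# P[X > x] for X ~ noncentral chi-squared(df, ncp)
.pnchisq_upper <- function(x, df, ncp) {
  if (ncp == 0) return(pchisq(x, df, lower.tail = FALSE))
  lam <- ncp / 2
  sdl <- sqrt(lam)
  jlo <- max(0, floor(lam - 12 * sdl - 20))
  jhi <- ceiling(lam + 12 * sdl + 20)
  j <- jlo:jhi
  w <- dpois(j, lam)
  sum(w * pchisq(x, df + 2 * j, lower.tail = FALSE))
}

.check_power_args <- function(w, n, df, alpha, power = NULL) {
  if (!is.null(w) && (is.na(w) || w < 0)) abort("`w` must be non-negative")
  if (!is.null(n) && (is.na(n) || n < 1)) abort("`n` must be at least 1")
  if (df < 1) abort("`df` must be at least 1")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (!is.null(power) && (power <= 0 || power >= 1)) {
    abort("`power` must be in (0, 1)")
  }
}

#' Power of a chi-squared test
#'
#' Power of the chi-squared test with `df` degrees of freedom at significance
#' level `alpha`, for Cohen effect size `w` and sample size `n`: the
#' probability that a noncentral chi-squared variable with noncentrality
#' `n * w^2` exceeds the central `1 - alpha` quantile.
#'
#' @param w Cohen's effect size w (a fraction; 0.30 denotes a "30%" effect).
#' @param n Sample size.
#' @param df Degrees of freedom.
#' @param alpha Significance level.
#' @return The power, accurate to well beyond six significant digits.
#' @examples
#' chisq_power(0.30, 1000, 100, 0.001)
#' @export
chisq_power <- function(w, n, df, alpha) {
  .check_power_args(w, n, df, alpha)
  crit <- qchisq(1 - alpha, df)
  .pnchisq_upper(crit, df, n * w^2)
}

#' Smallest sample size attaining a target power
#'
#' Minimal integer `n` with `chisq_power(w, n, df, alpha) >= power`, found by
#' doubling bracketing and integer bisection (power is increasing in `n`).
#'
#' @inheritParams chisq_power
#' @param power Target power.
#' @examples
#' required_n(0.30, 100, 0.001, 0.95)
#' @export
required_n <- function(w, df, alpha, power) {
  .check_power_args(w, NULL, df, alpha, power)
  if (w <= 0) abort("target power unreachable for w = 0")
  hi <- 1
  while (chisq_power(w, hi, df, alpha) < power) {
    hi <- hi * 2
    if (hi > 1e9) abort("target power unreachable below n = 1e9")
  }
  lo <- max(1, hi %/% 2)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (chisq_power(w, mid, df, alpha) >= power) hi <- mid else lo <- mid + 1
  }
  as.integer(hi)
}

#' Smallest detectable effect size at a given sample size
#'
#' The Cohen `w` at which the test attains exactly the target power, found by
#' root finding to a power residual below 1e-8.
#'
#' @inheritParams required_n
#' @param n Sample size.
#' @examples
#' detectable_effect(5000, 100, 0.001, 0.95) # about 0.13
#' @export
detectable_effect <- function(n, df, alpha, power) {
  .check_power_args(NULL, n, df, alpha, power)
  f <- function(w) chisq_power(w, n, df, alpha) - power
  root <- uniroot(f, c(1e-8, 50), tol = 1e-12)$root
  stopifnot(abs(f(root)) < 1e-8)
  root
}

#' Power analysis summary table
#'
#' Convenience wrapper assembling the quantities of a power specification
#' into one tidy row.
#'
#' @inheritParams chisq_power
#' @param power Target power used for `required_n` / `detectable_effect`.
#' @return A tibble with the inputs, the noncentrality `n * w^2`, the
#'   achieved power at (`w`, `n`), the minimum `n` for the target power at
#'   `w`, and the smallest detectable `w` at `n`.
#' @export
power_summary <- function(w, n, df, alpha, power) {
  tibble(w = w, n = n, df = df, alpha = alpha, target_power = power,
         noncentrality = n * w^2,
         achieved_power = chisq_power(w, n, df, alpha),
         required_n = required_n(w, df, alpha, power),
         detectable_w = detectable_effect(n, df, alpha, power))
}
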