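---
title: "Encrypted learning on simulated oncology cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encrypted learning on simulated oncology cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hecohort is a proof-of-concept learning system for a recurring problem in
personalized oncology: a small fraction of patients treated off-label respond
exceptionally well, and finding them requires pooling confidential records
across institutions. The package demonstrates that the core analyses — counting
exceptional responders month by month, and computing each patient's total drug
exposure — can run while every patient record stays encrypted under a
somewhat-homomorphic encryption scheme, with only the final aggregates ever
being decrypted. This vignette documents the models, the parameter choices, and
the boundaries of what the package's tests do and do not establish.

## The cohort model

`simulate_cohort()` draws a two-component survival mixture. Each patient is
exceptional with probability `p_exceptional` (default 0.05). Survival is normal
with mean 8 and standard deviation 1 month for standard patients, and 11 ± 1
months for exceptional responders; the "± 1" is read as the standard deviation
of a normal distribution, the only reading consistent with a generator
parameterized by a mean and a standard deviation. Months are fixed at 30 days,
so survival is drawn in days as `round(N(mu * 30, sigma * 30))`, truncated at 1
day. Start days are uniform over integer days in a 6-month enrollment window —
the finest granularity the simulation supports, rather than month-quantized
entry. The study spans 48 monthly visits.

Weight and dose distributions are not constrained by the scientific setting
beyond plausibility, so the package uses stationary truncated normals chosen
once as realistic adult oncology values: weight N(75, 10) kg truncated to
[40, 150] and recorded to 0.1 kg, dose N(2.5, 0.5) mg/kg truncated to (0, 6]
and recorded to 0.01 mg/kg. Any positive stationary
distribution would exercise the multiplicative pipeline identically; these
values matter only through the worst-case exposure bound used to size the
plaintext space.

**The flagging rule.** A patient's responder status must be derivable from
observed data at a given visit. The package flags an exceptional-group patient
at the study month containing day `start_day + survival_days` — the month in
which the unusually long survival has been fully observed. Flags are 0 before
that month and 1 from it onward (they are cumulative), so the homomorphic sum
of one month's flags across patients directly yields the cumulative
identification count for that month. The alternative reading — flagging while
alive upon crossing a pre-agreed survival threshold — would shift the curve
left by a constant; the death-month rule is the one that reproduces the
reported identification timeline (ten or more responders by about month 13,
all of them by about month 21) and matches the two-step construction of the
flag arrays. Simulated at the reference size (5000 patients, 20 seeds), the
mean milestones land near months 10 and 18.5, comfortably inside those bounds.

## The encryption scheme

The package implements the Fan–Vercauteren (FV/BFV) scheme over
`R_q = Z_q[X]/(X^n + 1)` from scratch: ternary secret keys, scale-Delta
plaintext encoding (`Delta = floor(q/t)`), centered-binomial errors
(`Binom(42, 1/2) - 21`, standard deviation about 3.24, approximating the
conventional sigma = 3.2 while sampling exactly in integers, reproducibly
across platforms), and base-256 relinearization after every multiplication.
Plaintexts are scalars encoded in the constant coefficient — one integer per
ciphertext, mirroring a per-value encryption design; there is no SIMD batching,
no bootstrapping, and no NTT-based *ciphertext representation*.

Two numerical choices deserve explanation:

* **Power-of-two modulus.** The ciphertext modulus is always `q = 2^B`. FV
  places no constraint on the form of `q`, and a power of two turns the
  `t/q` scale-and-round step at multiplication and decryption, and every mod-q
  reduction, into exact shifts and masks on the limb representation — the
  entire scheme then needs no big-integer division anywhere. Coefficients are
  stored in `[0, q)` as base-2^32 limb vectors and interpreted centered at
  decryption; a single fixed convention avoids sign errors.

* **Exact products via CRT + NTT.** Homomorphic multiplication needs exact
  integer products of degree-`n` polynomials with coefficients up to `q^2`
  (about 950 bits at the largest parameter set, with `n = 32768`). Schoolbook
  multiplication is quadratic in `n` and computationally out of reach there,
  so exact negacyclic products are computed by the Chinese remainder theorem
  over 31-bit NTT-friendly primes (`p ≡ 1 mod 2^17`) with Garner
  reconstruction. This is an exact multiplication *algorithm*, not an RNS
  ciphertext format: inputs and outputs remain single arbitrary-precision
  integers mod `q`, and results are bit-for-bit those of the schoolbook
  product (asserted against a brute-force oracle in the tests).

**Parameter selection.** `derive_params(security_bits, max_value, mult_depth)`
fixes `t = 2 * max_value + 1` (so signed values up to `max_value` are exactly
representable) and scans ring dimensions upward through an embedded table of
maximum `log2(q)` per (security level, `n`) taken from the published
homomorphic-encryption security standard for ternary secrets. At each
candidate `n` it evaluates a noise-growth model for a sequential
multiplication chain — fresh noise `~ 21 * (1 + 4 * sqrt(n))`, per-level growth
`log2(t) + 0.5 * log2(n) + 6.5` bits, a relinearization noise floor, and an
8-bit correctness margin — and accepts the first `n` whose bound fits. The
chosen `q_bits` adds 24 bits of headroom above the requirement, capped by the
security table. The per-level constant is calibrated to measured noise
trajectories: a worst-case expansion-factor analysis (delta = n) would declare
the 256-bit/depth-16 configuration infeasible even at `n = 32768`, while
measured growth is close to `t * sqrt(n)` per level; the calibrated model is
therefore backed by empirical depth certificates in the test suite (100
seeded depth-1 chains, 3 full depth-8 chains, and the depth-16 chain at the
256-bit level, all decrypting correctly with tens of bits of budget to spare).
`derive_params(verify = TRUE)` re-runs the certificate on demand.

Representative parameter sets:

| security | depth | n | log2(q) |
|---|---|---|---|
| 128 | 0 (counting) | 2048 | 54 |
| 128 | 1 (exposure) | 4096 | 80–98 |
| 256 | 8 | 16384 | 237 |
| 256 | 16 | 32768 | 458 |

**Noise accounting.** `noise_budget()` reports
`log2(q / (2 t |noise|))` from the decryption residual, clipped at zero. It
requires the secret key and exists for testing and diagnostics only, as does
`he_checked_decrypt()` (a known-plaintext audit that raises "noise exhausted"
on mismatch); neither is reachable from the analysis path, preserving the
design claim that analysts never see raw data.

## The encrypted analyses

**Counting.** `encrypt_flag_matrix()` encrypts each of `n_patients x 48`
flags individually (refusing parameter sets whose plaintext modulus could not
hold the final count), `count_responders_by_month()` sums each month's
ciphertext column — no secret key in scope — and `decrypt_counts()` performs
the single decryption of the 48 monthly aggregates. The decrypted curve is
asserted to equal the plaintext cumulative counts *exactly* on cohorts up to
n = 1000; for larger sweeps the proven-equal plaintext curve
(`responder_curve()`) stands in.

**Exposure.** Homomorphic arithmetic is exact integer arithmetic, so real
measurements use a fixed-point convention: weight in whole kilograms, dose in
tenths of mg/kg, totals in 0.1 mg units. Both factors are encrypted —
ciphertext-times-ciphertext is the strongest reading of multiplying a
patient's weight by the received dose under encryption — then monthly
products are accumulated homomorphically and decrypted once per patient.
Parameters must be derived with `max_value` at least
`exposure_bound(cohort) = study_months * max_weight * max_dose_tenths`
(432 000 fixed-point units at the defaults); undersized parameters fail at
setup rather than wrapping silently.

**Timing.** `timing_harness()` reproduces the shape of the reference timing
tables (per-stage wall-clock seconds, plus a 100-variables-per-analysis
extrapolation column that is by construction 100 x the addition time).
Wall-clock values are hardware-dependent diagnostics and are never asserted.

## Power analysis

Cohort sizes of 1000 and 5000 are justified by a chi-squared power analysis
with 100 degrees of freedom at significance 0.001 and target power 0.95,
taking the printed effect sizes "30%" and "13%" as Cohen's w = 0.30 and 0.13 —
the convention under which both printed figures are reproduced
simultaneously. The noncentral chi-squared upper tail is computed as a
Poisson(lambda/2)-weighted series of central chi-squared tails over a
12-standard-deviation index window, accurate to ~1e-12 and cross-checked in
the tests against both R's noncentral CDF and a Monte-Carlo oracle (10^5
draws of sums of squared shifted normals). `required_n()` brackets and
bisects on the integer sample size; `detectable_effect()` root-finds w to a
power residual below 1e-8. The contingency-table structure behind df = 100 is
taken as given.

## Reproducibility and problem sizes

Every random draw — key generation, encryption, simulation — flows through
R's RNG, so any analysis is a pure function of its master seed;
`split_seed()` fans a master seed into per-stage seeds. Test-suite problem
sizes were chosen to exercise every claim at full fidelity where feasible:
encrypted counting is verified on a complete 1000-patient, 48-month cohort;
encrypted exposure on 100 patients across all their on-study months; the
correctness sweeps use 1000 random payload pairs; milestone statistics use 20
cohorts of 5000 patients via the proven-equal plaintext curve. The depth-16
multiplication chain runs once per suite at the 256-bit level (a single chain
costs minutes at `n = 32768`).

## Limitations

The simulator emulates the *statistical* shape of the problem — mixture
survival, staggered entry, monthly measurements — not real-world messiness:
no missing visits, no measurement error in responder status, no censoring
other than study end, independent monthly weights rather than within-patient
trajectories. Passing tests therefore establish the correctness and
feasibility of the encrypted computation on data of this structure, not
clinical validity on real registries. Record linkage of encrypted
identifiers, multi-party key management, SIMD batching and genomic
summary-statistic safeguards are out of scope; per-value encryption makes the
pipelines slow by design, which is acceptable here because the encrypted
computations remain far faster than the months-long accrual of the survival
information they summarize.
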