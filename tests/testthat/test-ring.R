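# Negacyclic polynomial ring arithmetic underlying the scheme.

test_that("ring product matches closed forms", {
  # (1 + X)(1 - X) = 1 - X^2 = 2 in Z_q[X]/(X^2 + 1)
  a <- ring_element(c(1, 1), n = 2, q_bits = 20)
  b <- ring_element(c(1, -1), n = 2, q_bits = 20)
  expect_equal(ring_coeffs(ring_multiply(a, b)), c(2, 0))
  # multiplication by the constant 1 is the identity
  set.seed(21)
  v <- sample(-500:500, 16)
  x <- ring_element(v, n = 16, q_bits = 20)
  one <- ring_element(1, n = 16, q_bits = 20)
  expect_equal(ring_coeffs(ring_multiply(x, one)), ring_coeffs(x))
})

test_that("ring product agrees with a schoolbook negacyclic oracle", {
  set.seed(22)
  n <- 64; q_bits <- 20; q <- 2^q_bits
  for (trial in 1:5) {
    av <- as.numeric(sample(0:(q - 1), n, replace = TRUE))
    bv <- as.numeric(sample(0:(q - 1), n, replace = TRUE))
    got <- ring_coeffs(ring_multiply(ring_element(av, n, q_bits),
                                     ring_element(bv, n, q_bits)))
    want <- school_negacyclic(av, bv, q)
    # centered vs [0, q) representation
    expect_equal(got %% q, want)
  }
})

test_that("multi-limb arithmetic is consistent with the single-limb path", {
  # 2^20 divides 2^90, so results mod 2^90 reduced mod 2^20 must agree
  set.seed(23)
  n <- 64
  av <- as.numeric(sample(0:(2^20 - 1), n, replace = TRUE))
  bv <- as.numeric(sample(0:(2^20 - 1), n, replace = TRUE))
  r90 <- ring_coeffs(ring_multiply(ring_element(av, n, 90),
                                   ring_element(bv, n, 90)))
  r20 <- ring_coeffs(ring_multiply(ring_element(av, n, 20),
                                   ring_element(bv, n, 20)))
  expect_equal(r90 %% 2^20, r20 %% 2^20)
})

test_that("ring element validation catches bad inputs", {
  expect_error(ring_element(1:3, n = 3, q_bits = 20), "power of two")
  expect_error(ring_element(1:5, n = 4, q_bits = 20), "more coefficients")
  a <- ring_element(1:4, n = 4, q_bits = 20)
  b <- ring_element(1:8, n = 8, q_bits = 20)
  expect_error(ring_multiply(a, b), "different rings")
})
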