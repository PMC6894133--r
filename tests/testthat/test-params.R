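# Parameter derivation against the security table.

test_that("derived parameters satisfy their structural invariants", {
  for (cfg in list(c(128, 0), c(128, 1), c(128, 8), c(256, 8))) {
    p <- derive_params(cfg[1], max_value = 1000, mult_depth = cfg[2])
    expect_true(bitwAnd(p$n, p$n - 1) == 0)      # power-of-two ring
    expect_gt(p$t, 2 * p$max_value)              # signed payloads fit
    expect_gte(p$q_bits - log2(p$t), 1)          # Delta = floor(q/t) >= 2
    tab <- hecohort:::.sec_table[[as.character(cfg[1])]]
    expect_lte(p$q_bits, tab[[as.character(p$n)]])
  }
})

test_that("higher security never shrinks the ring at equal depth", {
  p128 <- derive_params(128, 1000, 8)
  p256 <- derive_params(256, 1000, 8)
  expect_gte(p256$n, p128$n)
})

test_that("unattainable depth requests fail with the binding constraint", {
  expect_error(derive_params(128, 1000, 40), "unattainable")
  expect_error(derive_params(256, 2^31, 0), "unattainable")
})

test_that("depth-1 parameters pass a fresh-encrypt/add/one-mult roundtrip sweep", {
  keys <- he_fixture(128, 1000, 1)
  M <- keys$params$max_value
  set.seed(31)
  for (i in 1:100) {
    m1 <- sample(-31:31, 1)
    m2 <- sample(-31:31, 1)
    c1 <- he_encrypt(keys$pk, m1)
    c2 <- he_encrypt(keys$pk, m2)
    expect_identical(he_decrypt(keys$sk, c1), m1 + 0)
    expect_identical(he_decrypt(keys$sk, he_add(c1, c2)), m1 + m2 + 0)
    expect_identical(he_decrypt(keys$sk, he_mult(c1, c2, keys$rlk)), m1 * m2 + 0)
  }
})
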