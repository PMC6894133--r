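# Core FV scheme behavior: keygen, encryption, homomorphic add/mult, noise.

test_that("key generation is deterministic from the seed", {
  p <- derive_params(128, 10, 0)
  k1 <- he_keygen(p, seed = 7)
  k2 <- he_keygen(p, seed = 7)
  k3 <- he_keygen(p, seed = 8)
  expect_identical(k1$sk$s, k2$sk$s)
  expect_identical(k1$pk$p0, k2$pk$p0)
  expect_identical(k1$rlk$b[[1]], k2$rlk$b[[1]])
  expect_false(identical(k1$sk$s, k3$sk$s))
})

test_that("encrypt/decrypt roundtrips across the plaintext range", {
  keys <- he_fixture()
  M <- keys$params$max_value
  expect_identical(he_decrypt(keys$sk, he_encrypt(keys$pk, 0)), 0)
  expect_identical(he_decrypt(keys$sk, he_encrypt(keys$pk, M)), M + 0)
  expect_identical(he_decrypt(keys$sk, he_encrypt(keys$pk, -M)), -M + 0)
  set.seed(41)
  ms <- sample(-M:M, 100)
  got <- vapply(ms, function(m) he_decrypt(keys$sk, he_encrypt(keys$pk, m)),
                numeric(1))
  expect_equal(got, as.numeric(ms))
})

test_that("encryption is randomized but decryption is stable", {
  keys <- he_fixture()
  c1 <- he_encrypt(keys$pk, 5)
  c2 <- he_encrypt(keys$pk, 5)
  expect_false(identical(c1$parts[[1]], c2$parts[[1]]))
  expect_identical(he_decrypt(keys$sk, c1), he_decrypt(keys$sk, c2))
})

test_that("out-of-range payloads are rejected", {
  keys <- he_fixture()
  expect_error(he_encrypt(keys$pk, keys$params$max_value + 1), "out of range")
})

test_that("homomorphic addition matches plaintext addition and commutes", {
  keys <- he_fixture()
  expect_identical(he_decrypt(keys$sk, he_add(he_encrypt(keys$pk, 0),
                                              he_encrypt(keys$pk, 0))), 0)
  expect_identical(he_decrypt(keys$sk, he_add(he_encrypt(keys$pk, 3),
                                              he_encrypt(keys$pk, 4))), 7)
  set.seed(42)
  for (i in 1:10) {
    m1 <- sample(-400:400, 1); m2 <- sample(-400:400, 1)
    a <- he_encrypt(keys$pk, m1); b <- he_encrypt(keys$pk, m2)
    expect_identical(he_decrypt(keys$sk, he_add(a, b)), m1 + m2 + 0)
    expect_identical(he_decrypt(keys$sk, he_add(a, b)),
                     he_decrypt(keys$sk, he_add(b, a)))
  }
})

test_that("summing a thousand encrypted 0/1 flags recovers the plaintext count", {
  keys <- he_fixture()
  set.seed(43)
  flags <- rbinom(1000, 1, 0.05)
  acc <- he_encrypt(keys$pk, flags[1])
  for (i in 2:length(flags)) acc <- he_add(acc, he_encrypt(keys$pk, flags[i]))
  expect_identical(he_decrypt(keys$sk, acc), sum(flags) + 0)
})

test_that("homomorphic multiplication matches plaintext multiplication", {
  keys <- he_fixture(L = 1)
  expect_identical(he_decrypt(keys$sk, he_mult(he_encrypt(keys$pk, 6),
                                               he_encrypt(keys$pk, 7),
                                               keys$rlk)), 42)
  set.seed(44)
  for (m in sample(-31:31, 5)) {
    expect_identical(he_decrypt(keys$sk, he_mult(he_encrypt(keys$pk, m),
                                                 he_encrypt(keys$pk, 0),
                                                 keys$rlk)), 0)
  }
})

test_that("size-3 products decrypt identically before and after relinearization", {
  keys <- he_fixture(L = 1)
  set.seed(45)
  for (i in 1:5) {
    m1 <- sample(-31:31, 1); m2 <- sample(-31:31, 1)
    raw <- he_mult_norelin(he_encrypt(keys$pk, m1), he_encrypt(keys$pk, m2))
    expect_length(raw$parts, 3)
    rel <- he_relinearize(raw, keys$rlk)
    expect_length(rel$parts, 2)
    expect_identical(he_decrypt(keys$sk, raw), m1 * m2 + 0)
    expect_identical(he_decrypt(keys$sk, raw), he_decrypt(keys$sk, rel))
  }
})

test_that("mismatched parameter sets are refused", {
  k1 <- he_fixture()
  k2 <- he_fixture(M = 10, seed = 101)
  expect_error(he_add(he_encrypt(k1$pk, 1), he_encrypt(k2$pk, 1)),
               "incompatible")
  expect_error(he_decrypt(k2$sk, he_encrypt(k1$pk, 1)), "incompatible")
})

test_that("checked decryption flags noise exhaustion without touching the analysis path", {
  keys <- he_fixture()
  ct <- he_encrypt(keys$pk, 9)
  expect_invisible(he_checked_decrypt(keys$sk, ct, 9))
  expect_error(he_checked_decrypt(keys$sk, ct, 10),
               class = "hecohort_noise_exhausted")
})

test_that("noise budget is positive when fresh and never increases", {
  keys <- he_fixture(L = 1)
  a <- he_encrypt(keys$pk, 3)
  b <- he_encrypt(keys$pk, 5)
  nb_fresh <- noise_budget(keys$sk, a)
  expect_gt(nb_fresh, 0)
  expect_lte(noise_budget(keys$sk, he_add(a, b)), nb_fresh)
  expect_lt(noise_budget(keys$sk, he_mult(a, b, keys$rlk)), nb_fresh)
})

test_that("noise grows faster under multiplication than under addition", {
  keys <- he_fixture(L = 1)
  set.seed(46)
  loss_add <- loss_mult <- numeric(100)
  for (i in 1:100) {
    m1 <- sample(-31:31, 1); m2 <- sample(-31:31, 1)
    a <- he_encrypt(keys$pk, m1); b <- he_encrypt(keys$pk, m2)
    nb <- min(noise_budget(keys$sk, a), noise_budget(keys$sk, b))
    loss_add[i] <- nb - noise_budget(keys$sk, he_add(a, b))
    loss_mult[i] <- nb - noise_budget(keys$sk, he_mult(a, b, keys$rlk))
  }
  expect_lt(mean(loss_add), mean(loss_mult))
})

test_that("multiplication chains decrypt correctly at the certified depths", {
  # depth 1: 100 seeded chains must essentially never fail
  keys <- he_fixture(L = 1)
  set.seed(47)
  ok <- 0
  for (i in 1:100) {
    ct <- he_mult(he_encrypt(keys$pk, 2), he_encrypt(keys$pk, 1), keys$rlk)
    ok <- ok + (he_decrypt(keys$sk, ct) == 2)
  }
  expect_gte(ok, 99)
  # depth 8: full-length chains on the depth-8 parameter set
  keys8 <- he_fixture(L = 8, seed = 102)
  for (trial in 1:3) {
    ct <- he_encrypt(keys8$pk, 2)
    for (i in 1:8) {
      ct <- he_mult(ct, he_encrypt(keys8$pk, 1), keys8$rlk)
    }
    expect_identical(he_decrypt(keys8$sk, ct), 2)
  }
})
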