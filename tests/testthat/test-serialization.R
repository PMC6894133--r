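# JSON envelopes for keys and ciphertexts.

test_that("key sets roundtrip exactly through their JSON envelopes", {
  keys <- he_fixture(M = 10, seed = 105)
  dir <- withr::local_tempdir()
  write_he_keys(keys, dir)
  back <- read_he_keys(dir)
  expect_identical(back$sk$s, keys$sk$s)
  expect_identical(back$pk$p0, keys$pk$p0)
  expect_identical(back$pk$p1, keys$pk$p1)
  expect_identical(back$rlk$b, keys$rlk$b)
  expect_identical(glance(back$params), glance(keys$params))
  # deserialized keys interoperate with the originals
  expect_identical(he_decrypt(back$sk, he_encrypt(keys$pk, 4)), 4)
  expect_identical(he_decrypt(keys$sk, he_encrypt(back$pk, -3)), -3)
})

test_that("public-only reads never touch the secret key file", {
  keys <- he_fixture(M = 10, seed = 105)
  dir <- withr::local_tempdir()
  write_he_keys(keys, dir)
  file.remove(file.path(dir, "secret_key.json"))
  pub <- read_he_keys(dir, which = "public")
  expect_null(pub$sk)
  expect_identical(he_decrypt(keys$sk, he_encrypt(pub$pk, 6)), 6)
})

test_that("ciphertexts roundtrip bit-exactly, including size-3 products", {
  keys <- he_fixture(M = 10, seed = 105)
  ct <- he_encrypt(keys$pk, 7)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_ciphertext(ct, path)
  back <- read_ciphertext(path)
  expect_identical(back$parts, ct$parts)
  expect_identical(he_decrypt(keys$sk, back), 7)
  k1 <- he_fixture(L = 1)
  raw <- he_mult_norelin(he_encrypt(k1$pk, 2), he_encrypt(k1$pk, 3))
  write_ciphertext(raw, path)
  expect_identical(he_decrypt(k1$sk, read_ciphertext(path)), 6)
})

test_that("corrupted envelopes are rejected", {
  keys <- he_fixture(M = 10, seed = 105)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_ciphertext(he_encrypt(keys$pk, 1), path)
  expect_error(hecohort:::.read_envelope(path, "public_key"), "envelope")
})
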