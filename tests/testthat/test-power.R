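# Noncentral chi-squared power analysis.

test_that("zero effect size gives power equal to the significance level", {
  for (alpha in c(0.05, 0.01, 0.001)) {
    expect_equal(chisq_power(0, 1000, 100, alpha), alpha, tolerance = 1e-12)
  }
})

test_that("the Poisson-mixture series matches R's noncentral machinery", {
  pts <- list(c(0.3, 1000, 100, 0.001), c(0.13, 5000, 100, 0.001),
              c(0.2, 400, 10, 0.05), c(0.05, 20000, 250, 0.01))
  for (p in pts) {
    crit <- qchisq(1 - p[4], p[3])
    ours <- chisq_power(p[1], p[2], p[3], p[4])
    ref <- pchisq(crit, p[3], ncp = p[2] * p[1]^2, lower.tail = FALSE)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("power agrees with the Monte-Carlo oracle", {
  set.seed(51)
  pts <- list(c(0.25, 800, 50, 0.01), c(0.3, 1000, 100, 0.001),
              c(0.15, 3000, 100, 0.005))
  for (p in pts) {
    expect_lt(abs(chisq_power(p[1], p[2], p[3], p[4]) -
                    mc_power(p[1], p[2], p[3], p[4])), 0.005)
  }
})

test_that("required_n is minimal and monotone in the effect size", {
  n_star <- required_n(0.2, 10, 0.01, 0.8)
  expect_lt(chisq_power(0.2, n_star - 1, 10, 0.01), 0.8)
  expect_gte(chisq_power(0.2, n_star, 10, 0.01), 0.8)
  ns <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5), required_n,
               integer(1), df = 100, alpha = 0.001, power = 0.95)
  expect_true(all(diff(ns) < 0))
  expect_error(required_n(0, 100, 0.001, 0.95), "unreachable")
})

test_that("detectable effect inverts required_n and shrinks with n", {
  w13 <- detectable_effect(5000, 100, 0.001, 0.95)
  w30 <- detectable_effect(1000, 100, 0.001, 0.95)
  expect_lt(w13, w30)
  for (w in c(0.15, 0.3)) {
    n_star <- required_n(w, 100, 0.001, 0.95)
    expect_lte(detectable_effect(n_star, 100, 0.001, 0.95), w + 1e-3)
  }
})

test_that("power increases strictly in n and w", {
  p1 <- chisq_power(0.2, 500, 100, 0.001)
  expect_gt(chisq_power(0.2, 1000, 100, 0.001), p1)
  expect_gt(chisq_power(0.3, 500, 100, 0.001), p1)
  expect_error(chisq_power(0.2, 500, 100, 2), "alpha")
})

test_that("power_summary assembles one coherent row", {
  s <- power_summary(0.3, 1000, 100, 0.001, 0.95)
  expect_identical(nrow(s), 1L)
  expect_equal(s$noncentrality, 1000 * 0.09)
  expect_equal(s$achieved_power, chisq_power(0.3, 1000, 100, 0.001))
})
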