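# Cohort simulator: reproducibility, distributional fidelity, flag logic.

test_that("identical parameters and seed give bit-identical cohorts", {
  c1 <- simulate_cohort(200, seed = 11)
  c2 <- simulate_cohort(200, seed = 11)
  c3 <- simulate_cohort(200, seed = 12)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("degenerate parameters collapse to the exact mixture means", {
  coh <- simulate_cohort(50, p_exceptional = 0, sigma_std = 0, sigma_exc = 0,
                         seed = 13)
  pts <- cohort_patients(coh)
  expect_true(all(pts$survival_days == 8 * 30))   # 8 months x 30 days
  expect_true(all(coh$flag == 0))                 # all-standard cohort
  expect_error(simulate_cohort(10, sigma_std = -1), "non-negative")
})

test_that("the exceptional fraction concentrates around 5 percent", {
  coh <- simulate_cohort(5000, seed = 14)
  nexc <- sum(cohort_patients(coh)$group == "exceptional")
  halfwidth <- 3 * sqrt(5000 * 0.05 * 0.95)
  expect_gte(nexc, 250 - halfwidth)
  expect_lte(nexc, 250 + halfwidth)
})

test_that("mixture mean survival approaches 0.95*8 + 0.05*11 months across seeds", {
  means <- vapply(1:50, function(s) {
    mean(cohort_patients(simulate_cohort(1000, seed = 2000 + s))$survival_days)
  }, numeric(1))
  expect_lt(abs(mean(means) - 244.5), 1) # 8.15 months at 30 days/month
})

test_that("group-wise survival parameters are recovered within 3 standard errors", {
  pts <- cohort_patients(simulate_cohort(5000, seed = 15))
  for (g in c("standard", "exceptional")) {
    x <- pts$survival_days[pts$group == g] / 30
    mu <- if (g == "standard") 8 else 11
    ng <- length(x)
    expect_lt(abs(mean(x) - mu), 3 * 1 / sqrt(ng) + 1 / 60) # + rounding slack
    expect_lt(abs(sd(x) - 1), 3 * 1 / sqrt(2 * (ng - 1)) + 1 / 60)
  }
})

test_that("flags are monotone and turn on at the death month", {
  coh <- toy_cohort(start_day = 0, survival_days = 330, group = "exceptional",
                    study_months = 15)
  first_on <- min(coh$month_index[coh$flag == 1])
  expect_identical(first_on, 11L) # 330 / 30
  sim <- simulate_cohort(300, seed = 16)
  mono <- tapply(sim$flag, sim$patient_id, function(f) all(diff(f) >= 0))
  expect_true(all(mono))
  # flagged total at the end of the study equals the exceptional-group count
  final <- sum(sim$flag[sim$month_index == max(sim$month_index)])
  expect_identical(final, sum(cohort_patients(sim)$group == "exceptional"))
})

test_that("weight and dose exist exactly for on-study months, within bounds", {
  coh <- simulate_cohort(200, seed = 17)
  on <- !is.na(coh$weight_kg)
  expect_identical(on, !is.na(coh$dose_mg_per_kg))
  death <- coh$start_day + coh$survival_days
  expect_identical(on, coh$month_index >= coh$start_day %/% 30 &
                     coh$month_index <= pmin((death - 1) %/% 30, 47))
  expect_true(all(coh$weight_kg[on] >= 40 & coh$weight_kg[on] <= 150))
  expect_true(all(coh$dose_mg_per_kg[on] > 0 & coh$dose_mg_per_kg[on] <= 6))
})

test_that("survival histogram bins, conserves and shows the elevated right tail", {
  one <- toy_cohort(0, 240, "standard", study_months = 10)
  h1 <- survival_histogram(one, bin_days = 30)
  expect_equal(h1$bin_start_days[h1$n == 1], 240)
  coh <- simulate_cohort(5000, seed = 18)
  h <- survival_histogram(coh, bin_days = 30)
  expect_identical(sum(h$n), 5000L)
  # P(survival > 10 months) under the mixture ~ 0.064, far above the pure
  # standard tail P(N(8,1) > 10) ~ 0.023
  p_tail <- mean(cohort_patients(coh)$survival_days > 300)
  p_mix <- 0.95 * pnorm(10, 8, 1, lower.tail = FALSE) +
    0.05 * pnorm(10, 11, 1, lower.tail = FALSE)
  expect_lt(abs(p_tail - p_mix), 3 * sqrt(p_mix * (1 - p_mix) / 5000))
  expect_gt(p_tail, pnorm(10, 8, 1, lower.tail = FALSE) + 0.02)
  # empty cohort -> empty histogram
  expect_identical(nrow(survival_histogram(toy_cohort(integer(0), integer(0),
                                                      character(0)))), 0L)
})

test_that("milestone lookup follows the curve semantics", {
  cv <- tibble::tibble(month = 0:4, count = c(0L, 0L, 2L, 2L, 3L))
  class(cv) <- c("identification_curve", class(tibble::tibble()))
  expect_identical(milestone_months(cv, 2), 2L)
  cv2 <- tibble::tibble(month = 0:3, count = c(0L, 1L, 3L, 3L))
  class(cv2) <- c("identification_curve", class(tibble::tibble()))
  expect_identical(milestone_months(cv2, "all"), 2L)
  expect_warning(m <- milestone_months(cv, 10),
                 class = "hecohort_milestone_unreached")
  expect_true(is.na(m))
})
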