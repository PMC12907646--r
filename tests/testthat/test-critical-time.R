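test_that("running slope normalization reproduces hand-computed fits", {
  # noiseless linear series: slope recovered exactly, adjusted = md0
  times <- seq(0, 5, by = 0.5)
  vals <- -4 - 0.8 * times
  res <- running_slope_and_adjust(times, vals)
  expect_null(res[[1]])                       # one visit: undefined
  for (v in 2:length(times)) {
    expect_equal(res[[v]]$slope_estimate, -0.8)
    expect_equal(res[[v]]$adjusted, rep(-4, v))
  }
  # 3-point worked set, normal-equations oracle
  res3 <- running_slope_and_adjust(0:2, c(-4.0, -4.5, -5.2))
  expect_equal(res3[[3]]$slope_estimate, -0.6)
  expect_equal(res3[[3]]$adjusted, c(-4.0, -3.9, -4.0))
  # masked tests are excluded from the fit
  resm <- running_slope_and_adjust(0:2, cbind(c(-4.0, -4.5, -5.2)),
                                   cbind(c(TRUE, FALSE, TRUE)))
  expect_equal(resm[[3]]$slope_estimate, (-5.2 + 4) / 2)
})

test_that("variability and reliability estimators follow their definitions", {
  expect_equal(estimate_variability(c(0, 2)), sqrt(2))   # n-1 denominator
  expect_equal(estimate_variability(rep(1.3, 5)), 0)
  expect_true(is.na(estimate_variability(3)))
  expect_equal(estimate_reliability(c(TRUE, TRUE, TRUE, FALSE)), 0.75)
  expect_equal(estimate_reliability(c(FALSE, FALSE)), 0)
  expect_equal(estimate_reliability(rep(TRUE, 8)), 1)
  expect_true(is.na(estimate_reliability(logical(0))))
})

test_that("consecutive-stability window follows the triplet rule", {
  # hand-checked window: (1.00, 1.02, 1.01) has range 0.02 <= 0.05 * mean
  expect_equal(find_critical_time_consecutive(0:4, c(1.00, 1.02, 1.01, 1.3, 1)),
               2)
  # identical values, including all-zero, qualify at the third defined visit
  expect_equal(find_critical_time_consecutive(0:4, rep(2, 5)), 2)
  expect_equal(find_critical_time_consecutive(0:4, rep(0, 5)), 2)
  # undefined visits are skipped without resetting the window
  expect_equal(find_critical_time_consecutive(0:4, c(1.00, NA, 1.02, NA, 1.01)),
               4)
  # censored when no triplet qualifies
  expect_true(is.na(find_critical_time_consecutive(0:3, c(1, 2, 1, 2))))
  expect_error(find_critical_time_consecutive(0:2, rep(1, 3), tolerance = 0),
               "tolerance")
})

test_that("ground-truth window requires three consecutive in-band estimates", {
  # first qualifying triplet is visits 1-3 (visit 0 is out of band)
  expect_equal(
    find_critical_time_ground_truth(0:3, c(0.94, 0.96, 1.00, 1.04), 1), 3)
  # estimates equal to truth from the start: third defined visit
  expect_equal(find_critical_time_ground_truth(0:4, rep(1, 5), 1), 2)
  # an eligible out-of-band estimate resets the run; a gap does not
  expect_equal(
    find_critical_time_ground_truth(0:5, c(1, 1, 0.8, 1, 1, 1), 1), 5)
  expect_equal(
    find_critical_time_ground_truth(0:5, c(1, NA, 1, NA, NA, 1), 1), 5)
})

test_that("window scanners agree with a naive re-scan oracle on gapped series", {
  set.seed(1)
  for (rep in 1:1000) {
    len <- sample(5:40, 1)
    times <- as.numeric(sort(sample(0:100, len)))
    e <- random_gapped_series(len)
    truth <- stats::runif(1, 0.5, 3)
    expect_identical(find_critical_time_consecutive(times, e),
                     oracle_consecutive(times, e))
    expect_identical(find_critical_time_ground_truth(times, e, truth),
                     oracle_ground_truth(times, e, truth))
  }
})

test_that("raising the tolerance never delays a critical time", {
  set.seed(2)
  for (rep in 1:200) {
    e <- random_gapped_series(30)
    t5 <- find_critical_time_consecutive(0:29, e, 0.05)
    t10 <- find_critical_time_consecutive(0:29, e, 0.10)
    if (!is.na(t5)) {
      expect_false(is.na(t10))
      expect_lte(t10, t5)
    }
  }
})

test_that("re-fitting a slope to adjusted values yields zero", {
  set.seed(3)
  times <- seq(0, 10, by = 0.5)
  vals <- -3 - 0.6 * times + rnorm(length(times), 0, 1.5)
  res <- running_slope_and_adjust(times, vals)
  for (v in c(5, 11, 21)) {
    fit <- lm(res[[v]]$adjusted ~ times[seq_len(v)])
    expect_equal(unname(coef(fit)[2]), 0, tolerance = 1e-10)
  }
})

test_that("cohort critical times match the single-series route", {
  pop <- test_population(30, seed = 4)
  set.seed(4)
  core <- simulate_core(pop, vf_schedule("long_term"))
  perm <- derive_permutation(core, permutation_spec(2, 2))
  ct <- compute_critical_times(perm)
  for (i in c(1, 13, 30)) {
    re <- running_estimates(perm, subject_id = i)
    v_est <- ifelse(re$window_eligible, re$variability_estimate, NA)
    r_est <- ifelse(re$window_eligible, re$reliability_estimate, NA)
    expect_identical(ct$tcv[i], find_critical_time_consecutive(re$time, v_est))
    expect_identical(ct$tgv[i],
                     find_critical_time_ground_truth(re$time, v_est,
                                                     pop$sigma_db[i]))
    expect_identical(ct$tcr[i], find_critical_time_consecutive(re$time, r_est))
    expect_identical(ct$tgr[i],
                     find_critical_time_ground_truth(re$time, r_est,
                                                     pop$reliability[i]))
  }
})

test_that("floor case: perfect subject reaches TcR at the third visit", {
  pop <- data.frame(subject_id = 1L, md0_db = -4, slope_db_per_year = 0,
                    sigma_db = 1e-9, reliability = 1)
  class(pop) <- c("vf_population", "data.frame")
  set.seed(5)
  core <- simulate_core(pop, vf_schedule("short_term"))
  ct <- compute_critical_times(core, permutation_spec(1, 1))
  expect_equal(ct$tcr, 2)   # third visit, two intervals after day 0
  expect_equal(ct$tcv, 3)   # variability defined from day 1, triplet days 1-3
  # long-term 3-monthly floor: third visit at 0.5 years
  set.seed(5)
  core_l <- simulate_core(pop, vf_schedule("long_term"))
  ct_l <- compute_critical_times(core_l, permutation_spec(1, 1))
  expect_equal(ct_l$tcr, 0.5)
})

test_that("end-of-series variability estimates recover sigma", {
  # subjects in a narrow sigma band; the short-term 4-test daily series has
  # 112 tests, where the sample SD's small-sample bias factor
  # c4 = sqrt(2/(n-1)) * gamma(n/2) / gamma((n-1)/2) is ~0.998
  pop <- make_fixed_population(rep(-4, 400), rep(0, 400), rep(1.5, 400),
                               rep(1, 400))
  set.seed(6)
  core <- simulate_core(pop, vf_schedule("short_term"))
  final <- vapply(seq_len(400), function(i)
    running_estimates(core, i)$variability_estimate[28], numeric(1))
  n <- 112
  c4 <- sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  expect_equal(mean(final) / 1.5, c4, tolerance = 0.005)
})
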