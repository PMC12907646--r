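# minimal hand-built critical-times table for summary-level tests
make_ct <- function(tcv, tgv = tcv, tcr = tcv, tgr = tcv,
                    diff_var = 0, diff_rel = 0, k = 1L, m = 1L,
                    times = 0:27) {
  n <- length(tcv)
  out <- data.frame(subject_id = seq_len(n), tests_per_visit = k,
                    interval_multiplier = m, interval = "daily",
                    tcv = tcv, tgv = tgv, tcr = tcr, tgr = tgr,
                    var_at_tcv_db = NA_real_, rel_at_tcr = NA_real_,
                    diff_var_db = diff_var, diff_rel = diff_rel)
  class(out) <- c("vf_critical_times", "data.frame")
  attr(out, "visit_times") <- times
  attr(out, "time_unit") <- "days"
  attr(out, "family") <- "short_term"
  out
}

test_that("permutation summaries use detected subjects and type-7 quantiles", {
  ct <- make_ct(c(1, 2, 3, 4, 100, NA))
  s <- summarize_critical_times(ct, "tcv")
  expect_equal(s$n_detected, 5)
  expect_equal(s$median, 3)              # hand quantile check
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  # censored subjects count in the detection-curve denominator
  expect_equal(s$detection_curve$proportion[s$detection_curve$time == 4],
               4 / 6)
  expect_true(all(diff(s$detection_curve$proportion) >= 0))
  # all censored: no quantiles, flat zero curve
  s0 <- summarize_critical_times(make_ct(rep(NA_real_, 4)), "tcv")
  expect_equal(s0$n_detected, 0)
  expect_true(is.na(s0$median))
  expect_true(all(s0$detection_curve$proportion == 0))
})

test_that("group comparisons reproduce a hand-rank Kruskal-Wallis oracle", {
  ct <- rbind(make_ct(c(1, 2, 3), k = 1L), make_ct(c(4, 5, 6), k = 2L))
  class(ct) <- c("vf_critical_times", "data.frame")
  res <- compare_groups(ct, "tcv", "tests_per_visit")
  # brute-force rank-sum oracle: H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1)
  r <- rank(c(1, 2, 3, 4, 5, 6))
  H <- 12 / (6 * 7) * (sum(r[1:3])^2 / 3 + sum(r[4:6])^2 / 3) - 3 * 7
  expect_equal(res$statistic, H)
  expect_equal(res$df, 1)
  # identical distributions: H ~ 0, p ~ 1
  ct2 <- rbind(make_ct(c(1, 2, 3), k = 1L), make_ct(c(1, 2, 3), k = 2L))
  class(ct2) <- c("vf_critical_times", "data.frame")
  res2 <- compare_groups(ct2, "tcv", "tests_per_visit")
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1, tolerance = 1e-12)
  expect_error(compare_groups(make_ct(1:3), "tcv", "tests_per_visit"),
               "two groups")
})

test_that("difference-from-truth pairs subjects and matches a hand t-test", {
  # only subjects with both critical times detected enter
  ct <- make_ct(tcv = c(1, 2, NA, 3), tgv = c(1, NA, 2, 3),
                diff_var = c(0.1, 9, 9, -0.1))
  d <- difference_from_truth(ct, "variability")
  expect_equal(d$n, 2)
  expect_equal(sort(d$differences), c(-0.1, 0.1))
  # toy set vs hand t statistic: mean 0.1, sd 0.2, t = 0.1/(0.2/sqrt(3))
  ct3 <- make_ct(tcv = c(1, 1, 1), tgv = c(1, 1, 1),
                 diff_var = c(0.1, -0.1, 0.3))
  d3 <- difference_from_truth(ct3, "variability")
  expect_equal(d3$t_statistic, 0.1 / (0.2 / sqrt(3)))
  # degenerate: all differences zero -> t undefined, not an error
  dz <- difference_from_truth(make_ct(c(1, 2), diff_var = c(0, 0)),
                              "variability")
  expect_true(is.na(dz$t_statistic))
  # empty filtered set
  de <- difference_from_truth(make_ct(NA_real_), "reliability")
  expect_equal(de$n, 0)
})

test_that("predictor regressions behave at the exact and degenerate limits", {
  pop <- make_fixed_population(md0 = c(-2, -4, -6, -8),
                               slope = c(-0.1, -0.2, -0.3, -0.4),
                               sigma = 1:4, reliability = rep(0.9, 4))
  # outcome exactly linear in sigma: R^2 = 1, coefficient recovered
  # (the fixture's predictors are mutually collinear, so the fit is exact
  # for all of them; summary.lm warns about the perfect fit)
  ct <- make_ct(tcv = 2 * (1:4) + 5)
  reg <- suppressWarnings(regress_predictors(ct, pop, "tcv"))
  sig <- reg[reg$predictor == "sigma_db", ]
  expect_equal(sig$coefficient, 2)
  expect_equal(sig$r_squared, 1)
  # constant outcome: flat fit, nothing explained
  regc <- regress_predictors(make_ct(rep(3, 4)), pop, "tcv")
  expect_true(all(regc$coefficient[!regc$degenerate] == 0))
  expect_true(all(regc$r_squared[!regc$degenerate] == 0))
  # zero-variance predictor flagged as degenerate
  rel <- reg[reg$predictor == "reliability", ]
  expect_true(rel$degenerate)
  expect_true(is.na(rel$coefficient))
})

test_that("summary tables have the interval-by-tests shape", {
  set.seed(7)
  pop <- test_population(60, seed = 7)
  core <- simulate_core(pop, vf_schedule("short_term"))
  ct <- compute_critical_times_all(core)
  tab <- critical_time_table(ct, "tcr")
  expect_equal(names(tab), c("interval", "k1", "k2", "k3", "k4", "p_by_tests"))
  expect_equal(tab$interval,
               c("daily", "every 2 days", "every 4 days", "p_by_interval"))
  expect_match(tab$k1[1], "^\\d+(\\.\\d+)? \\(")
  curves <- detection_curves(ct, "tcv")
  expect_equal(sort(unique(curves$tests_per_visit)), 1:4)
  expect_true(all(curves$proportion >= 0 & curves$proportion <= 1))
})
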