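#' Running progression-slope estimate and normalized values
#'
#' Clinical reality is that the true progression rate is unknowable, so
#' long-term series are normalized with a running estimate: at each visit
#' `v`, an ordinary-least-squares slope is fitted to all valid
#' `(time, md)` pairs observed up to and including `v`, and all those
#' values are adjusted as `md - slope * time`. The adjustment is
#' undefined until valid data exist at two distinct visit times.
#'
#' @param times Visit times (one per visit, strictly increasing).
#' @param values Matrix of md values, visits x tests (a vector is treated
#'   as one test per visit).
#' @param mask Logical matrix like `values`; `FALSE` marks discarded
#'   (unreliable) tests. Default: all valid.
#'
#' @return A list with one element per visit: `NULL` while the
#'   adjustment is undefined, otherwise a list with `slope_estimate`
#'   (dB per time unit) and `adjusted` (vector of all valid adjusted
#'   values up to that visit, in visit-then-test order).
#' @examples
#' running_slope_and_adjust(0:2, c(-4.0, -4.5, -5.2))[[3]]
#' @export
running_slope_and_adjust <- function(times, values, mask = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  mask <- as.matrix(mask)
  stopifnot(length(times) == nrow(values), all(dim(mask) == dim(values)))
  out <- vector("list", length(times))
  for (v in seq_along(times)) {
    upto <- seq_len(v)
    ok <- which(mask[upto, , drop = FALSE], arr.ind = TRUE)
    if (nrow(ok) >= 2L) {
      ok <- ok[order(ok[, 1], ok[, 2]), , drop = FALSE]
      t_ok <- times[ok[, 1]]
      y_ok <- values[upto, , drop = FALSE][ok]
      if (length(unique(t_ok)) >= 2L) {
        slope <- sum((t_ok - mean(t_ok)) * (y_ok - mean(y_ok))) /
          sum((t_ok - mean(t_ok))^2)
        out[[v]] <- list(slope_estimate = slope,
                         adjusted = y_ok - slope * t_ok)
      }
    }
  }
  out
}

#' Variability estimate from adjusted values
#'
#' Sample standard deviation (n - 1 denominator) of all valid (adjusted)
#' mean-deviation values accumulated so far; `NA` with fewer than two
#' values.
#'
#' @param values Numeric vector of valid (adjusted) md values.
#' @return Standard deviation in dB, or `NA`.
#' @export
estimate_variability <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  stats::sd(values)
}

#' Reliability estimate from the usability mask
#'
#' Cumulative proportion of reliable results among all administered tests
#' (discarded tests count in the denominator).
#'
#' @param mask Logical vector/matrix of usability flags for all tests
#'   administered up to the current visit.
#' @return Proportion in `[0, 1]`, or `NA` for zero tests.
#' @export
estimate_reliability <- function(mask) {
  if (length(mask) == 0L) return(NA_real_)
  mean(as.logical(mask))
}

# ---- rolling-window scanners (vectorized production path) -------------------
#
# E: subjects x visits matrix of running estimates, NA = this visit is
# ineligible for the window (estimate undefined, or no valid result at the
# visit). Ineligible visits are skipped without resetting the window.

scan_consecutive <- function(E, times, tolerance) {
  stopifnot(tolerance > 0)
  n <- nrow(E)
  e1 <- e2 <- rep(NA_real_, n)          # last two eligible estimates
  hit_time <- hit_est <- rep(NA_real_, n)
  for (v in seq_len(ncol(E))) {
    ev <- E[, v]
    open <- is.na(hit_time)
    cand <- open & !is.na(ev) & !is.na(e1) & !is.na(e2)
    if (any(cand)) {
      spread <- pmax(e1, e2, ev) - pmin(e1, e2, ev)
      q <- cand & spread <= tolerance * (e1 + e2 + ev) / 3
      hit_time[q] <- times[v]
      hit_est[q] <- ev[q]
    }
    sh <- is.na(hit_time) & !is.na(ev)
    e2[sh] <- e1[sh]
    e1[sh] <- ev[sh]
  }
  list(time = hit_time, estimate = hit_est)
}

scan_ground_truth <- function(E, truth, times, tolerance) {
  stopifnot(tolerance > 0, all(truth > 0))
  n <- nrow(E)
  run <- integer(n)
  hit_time <- hit_est <- rep(NA_real_, n)
  for (v in seq_len(ncol(E))) {
    ev <- E[, v]
    eligible <- !is.na(ev)
    inband <- eligible & abs(ev - truth) <= tolerance * truth
    run[eligible & !inband] <- 0L
    open <- is.na(hit_time)
    adv <- open & inband
    run[adv] <- run[adv] + 1L
    q <- open & run >= 3L
    hit_time[q] <- times[v]
    hit_est[q] <- ev[q]
  }
  list(time = hit_time, estimate = hit_est)
}

#' Critical time under the consecutive-stability criterion
#'
#' Scans running estimates in visit order for the first three consecutive
#' eligible estimates within tolerance of each other, operationalized as
#' `max - min <= tolerance * mean` over the triplet (a triplet of
#' identical values, including zeros, qualifies). Visits with an
#' undefined estimate (`NA`) are skipped without resetting the window.
#' The critical time is the time of the third visit of the first
#' qualifying triplet; `NA` means censored (never met within the
#' schedule horizon).
#'
#' @param times Visit times.
#' @param estimates Running estimates, one per visit, `NA` where
#'   undefined/ineligible.
#' @param tolerance Relative tolerance (default 0.05).
#'
#' @return The critical time, or `NA` if censored.
#' @examples
#' find_critical_time_consecutive(0:3, c(1.00, 1.02, 1.01, 0.9))
#' @export
find_critical_time_consecutive <- function(times, estimates, tolerance = 0.05) {
  stopifnot(length(times) == length(estimates))
  scan_consecutive(matrix(estimates, nrow = 1), times, tolerance)$time
}

#' Critical time relative to the ground truth
#'
#' First time at which three consecutive eligible estimates each lie
#' within `tolerance * truth` of the ground-truth parameter; the critical
#' time is the third visit of that run. Undefined visits are skipped
#' without resetting; an eligible out-of-band estimate resets the run.
#'
#' @param times Visit times.
#' @param estimates Running estimates, `NA` where undefined/ineligible.
#' @param truth Ground-truth value (> 0).
#' @param tolerance Relative tolerance (default 0.05).
#'
#' @return The critical time, or `NA` if censored.
#' @examples
#' find_critical_time_ground_truth(0:3, c(0.94, 0.96, 1.00, 1.04), 1)
#' @export
find_critical_time_ground_truth <- function(times, estimates, truth,
                                            tolerance = 0.05) {
  stopifnot(length(times) == length(estimates), length(truth) == 1L)
  scan_ground_truth(matrix(estimates, nrow = 1), truth, times, tolerance)$time
}

# ---- cohort-level running estimates (cumulative-sum engine) -----------------
#
# Computes, for every subject and retained visit, the running variability
# estimate (normalized by the running OLS slope for long-term cohorts, raw
# for short-term), the running reliability estimate, and window eligibility.
# Algebra: with cumulative sums over valid points (N, St, Sy, St2, Sy2, Sty),
# the OLS slope is b = (N*Sty - St*Sy) / (N*St2 - St^2) and the sum of
# squares of b-adjusted values about their mean is
# Sy2 - 2b*Sty + b^2*St2 - (Sy - b*St)^2 / N.
cohort_running_estimates <- function(cohort) {
  normalize <- cohort$schedule$family == "long_term"
  d <- dim(cohort$md)
  n <- d[1]; V <- d[2]; k <- d[3]
  times <- cohort$visit_times
  N <- St <- Sy <- St2 <- Sy2 <- Sty <- numeric(n)
  distinct <- integer(n)
  Var <- Rel <- Slope <- matrix(NA_real_, n, V)
  Nvalid <- matrix(0L, n, V)
  Fresh <- matrix(FALSE, n, V)          # visit produced >= 1 valid result
  for (v in seq_len(V)) {
    t <- times[v]
    y <- cohort$md[, v, , drop = FALSE];       dim(y) <- c(n, k)
    r <- cohort$reliable[, v, , drop = FALSE]; dim(r) <- c(n, k)
    y[!r] <- 0
    cnt <- rowSums(r)
    N <- N + cnt
    Sy <- Sy + rowSums(y)
    Sy2 <- Sy2 + rowSums(y * y)
    St <- St + t * cnt
    St2 <- St2 + t * t * cnt
    Sty <- Sty + t * rowSums(y)
    distinct <- distinct + (cnt > 0L)
    Nvalid[, v] <- N
    Fresh[, v] <- cnt > 0L
    Rel[, v] <- N / (k * v)
    if (normalize) {
      den <- N * St2 - St * St
      def_slope <- distinct >= 2L & den > 0
      b <- ifelse(def_slope, (N * Sty - St * Sy) / den, NA_real_)
      Slope[, v] <- b
      def <- def_slope & N >= 2L
      ssq <- Sy2 - 2 * b * Sty + b * b * St2 - (Sy - b * St)^2 / N
      Var[, v] <- ifelse(def, sqrt(pmax(ssq, 0) / (N - 1L)), NA_real_)
    } else {
      def <- N >= 2L
      ssq <- Sy2 - Sy^2 / pmax(N, 1L)
      Var[, v] <- ifelse(def, sqrt(pmax(ssq, 0) / pmax(N - 1L, 1L)), NA_real_)
    }
  }
  list(times = times, variability = Var, reliability = Rel, slope = Slope,
       n_valid = Nvalid, fresh = Fresh)
}

#' Per-visit running estimates for one subject
#'
#' Convenience view of the running estimation process for a single
#' subject of a cohort (as in a worked single-patient illustration):
#' running slope, variability and reliability estimates per visit, with
#' eligibility of each visit for the rolling windows (a visit with no
#' valid result is skipped by the window scans without resetting them).
#'
#' @param cohort A `vf_cohort`.
#' @param subject_id Subject identifier (row of the population).
#'
#' @return A `data.frame` with columns `time`, `n_valid_tests`
#'   (cumulative), `slope_estimate`, `variability_estimate`,
#'   `reliability_estimate` and `window_eligible`.
#' @export
running_estimates <- function(cohort, subject_id = 1L) {
  i <- match(subject_id, cohort$population$subject_id)
  if (is.na(i)) stop("running_estimates: unknown subject_id")
  est <- cohort_running_estimates(cohort)
  data.frame(time = est$times,
             n_valid_tests = est$n_valid[i, ],
             slope_estimate = est$slope[i, ],
             variability_estimate = est$variability[i, ],
             reliability_estimate = est$reliability[i, ],
             window_eligible = est$fresh[i, ])
}

#' Critical times for every subject of a cohort permutation
#'
#' Computes, per subject, the four critical times: `tcv`/`tcr` from the
#' consecutive-stability criterion on the running variability/reliability
#' estimates, and `tgv`/`tgr` from the ground-truth criterion against the
#' subject's true `sigma_db` and `reliability`. Long-term cohorts are
#' normalized with the running OLS slope before variability estimation;
#' short-term cohorts use raw values (daily progression is negligible, so
#' normalization is deliberately skipped there). `NA` critical times are
#' censored (criterion never met within the schedule horizon).
#'
#' @param cohort A `vf_cohort` (a core series or a derived permutation).
#' @param spec Optional [permutation_spec()]; when supplied, the
#'   permutation is derived from `cohort` first.
#' @param tolerance Relative rolling-window tolerance (default 0.05;
#'   the alternative analysis uses 0.10).
#'
#' @return A `data.frame` of class `vf_critical_times` with one row per
#'   subject: `subject_id`, `tests_per_visit`, `interval_multiplier`,
#'   `interval`, `tcv`, `tgv`, `tcr`, `tgr` (time units of the schedule,
#'   `NA` = censored), `var_at_tcv_db`, `rel_at_tcr`, `diff_var_db`
#'   (estimate at TcV minus true sigma) and `diff_rel` (estimate at TcR
#'   minus true reliability). Attributes: `tolerance`, `family`,
#'   `time_unit`, `visit_times`.
#' @examples
#' set.seed(1)
#' core <- simulate_core(sample_population(20), vf_schedule("short_term"))
#' ct <- compute_critical_times(core, permutation_spec(1, 1))
#' head(ct)
#' @export
compute_critical_times <- function(cohort, spec = NULL, tolerance = 0.05) {
  if (!is.null(spec)) cohort <- derive_permutation(cohort, spec)
  if (!(is.numeric(tolerance) && length(tolerance) == 1L &&
        tolerance > 0 && tolerance < 1))
    stop("compute_critical_times: tolerance must be in (0, 1)")
  est <- cohort_running_estimates(cohort)
  # skip rule: visits with no valid result carry no estimate into the windows
  Var <- ifelse(est$fresh, est$variability, NA_real_)
  Rel <- ifelse(est$fresh, est$reliability, NA_real_)
  pop <- cohort$population
  cv <- scan_consecutive(Var, est$times, tolerance)
  gv <- scan_ground_truth(Var, pop$sigma_db, est$times, tolerance)
  cr <- scan_consecutive(Rel, est$times, tolerance)
  gr <- scan_ground_truth(Rel, pop$reliability, est$times, tolerance)
  out <- data.frame(subject_id = pop$subject_id,
                    tests_per_visit = cohort$tests_per_visit,
                    interval_multiplier = cohort$interval_multiplier,
                    interval = interval_label(cohort$schedule$family,
                                              cohort$interval_multiplier),
                    tcv = cv$time, tgv = gv$time,
                    tcr = cr$time, tgr = gr$time,
                    var_at_tcv_db = cv$estimate,
                    rel_at_tcr = cr$estimate,
                    diff_var_db = cv$estimate - pop$sigma_db,
                    diff_rel = cr$estimate - pop$reliability)
  class(out) <- c("vf_critical_times", "data.frame")
  attr(out, "tolerance") <- tolerance
  attr(out, "family") <- cohort$schedule$family
  attr(out, "time_unit") <- cohort$schedule$time_unit
  attr(out, "visit_times") <- cohort$visit_times
  out
}

#' Critical times across all permutations of a core series
#'
#' Applies [compute_critical_times()] to each testing permutation derived
#' from one core series (subsetting, never re-simulation) and stacks the
#' results.
#'
#' @param core A core `vf_cohort` from [simulate_core()].
#' @param tolerance Rolling-window tolerance (default 0.05).
#' @param permutations List of [permutation_spec()]s (default all 12).
#'
#' @return A stacked `vf_critical_times` data frame (one row per subject
#'   and permutation) with attributes `tolerance`, `family`, `time_unit`
#'   and `visit_times` (the core grid).
#' @export
compute_critical_times_all <- function(core, tolerance = 0.05,
                                       permutations = all_permutations()) {
  parts <- lapply(permutations, function(sp)
    compute_critical_times(core, sp, tolerance))
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("vf_critical_times", "data.frame")
  attr(out, "tolerance") <- tolerance
  attr(out, "family") <- core$schedule$family
  attr(out, "time_unit") <- core$schedule$time_unit
  attr(out, "visit_times") <- core$visit_times
  out
}
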