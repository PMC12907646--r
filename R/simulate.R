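#' Simulate the core longitudinal dataset for a cohort
#'
#' Generates the complete ("core") series for every subject: at each
#' visit time \eqn{t_i} of the schedule, `tests_per_visit` mean-deviation
#' results \eqn{MD_{ij} = MD_0 + r t_i + \epsilon_{ij}} with
#' \eqn{\epsilon_{ij}} i.i.d. \eqn{N(0, \sigma^2)}, plus an independent
#' Bernoulli(reliability) usability flag per test. For the long-term
#' schedule visit times are in years and the progression rate applies
#' directly; for the short-term schedule times are in days and the slope
#' contributes `slope * day / 365`, so the decision not to normalize
#' short-term series is an analysis choice, not a property of the data.
#'
#' Unreliable tests are generated then masked; their values are never
#' used downstream but administered tests count in reliability
#' denominators.
#'
#' @param population A `vf_population` data frame
#'   ([sample_population()]).
#' @param schedule A [vf_schedule()].
#'
#' @return An object of class `vf_cohort`: a list with
#'   `md` (subjects x visits x tests array, dB),
#'   `reliable` (same shape, logical),
#'   `schedule`, `population`, `tests_per_visit`,
#'   `interval_multiplier` (1 for a core series) and `visit_times`.
#' @examples
#' set.seed(1)
#' cohort <- simulate_core(sample_population(3), vf_schedule("short_term"))
#' dim(cohort$md)
#' @export
simulate_core <- function(population, schedule) {
  stopifnot(inherits(schedule, "vf_schedule"))
  n <- nrow(population)
  times <- schedule$visit_times
  V <- length(times)
  k <- schedule$tests_per_visit
  t_years <- if (schedule$time_unit == "years") times else times / 365
  # fixed draw order: all noise, then all reliability flags
  eps <- array(stats::rnorm(n * V * k), dim = c(n, V, k))
  trend <- outer(population$md0_db, rep(1, V)) +
    outer(population$slope_db_per_year, t_years)
  md <- array(0, dim = c(n, V, k))
  for (j in seq_len(k))
    md[, , j] <- trend + population$sigma_db * eps[, , j]
  reliable <- array(stats::runif(n * V * k) < rep(population$reliability, V * k),
                    dim = c(n, V, k))
  structure(list(md = md, reliable = reliable,
                 schedule = schedule, population = population,
                 tests_per_visit = k, interval_multiplier = 1L,
                 visit_times = times),
            class = "vf_cohort")
}

#' @export
print.vf_cohort <- function(x, ...) {
  cat(sprintf("Visual-field cohort: %d subjects, %s plan, %d visits x %d tests/visit (every %d%s visit)\n",
              dim(x$md)[1], x$schedule$family, dim(x$md)[2], x$tests_per_visit,
              x$interval_multiplier,
              switch(as.character(x$interval_multiplier), "1" = "st", "2" = "nd",
                     "3" = "rd", "th")))
  invisible(x)
}

#' Derive a testing permutation from a core series
#'
#' Restricts a core cohort to a sparser condition by subsetting (never by
#' re-simulation): visits at indices 1, 1+m, 1+2m, ... of the core grid
#' and the first `k` test columns of each retained visit. Visit times are
#' preserved, not re-indexed, so the sparser condition's data are an
#' exact subset of the denser one's.
#'
#' @param cohort A `vf_cohort` from [simulate_core()] (a core series,
#'   i.e. `interval_multiplier == 1`).
#' @param spec A [permutation_spec()].
#'
#' @return A `vf_cohort` restricted to the permutation.
#' @examples
#' set.seed(1)
#' core <- simulate_core(sample_population(2), vf_schedule("long_term"))
#' yearly <- derive_permutation(core, permutation_spec(1, 4))
#' yearly$visit_times[1:3]
#' @export
derive_permutation <- function(cohort, spec) {
  stopifnot(inherits(cohort, "vf_cohort"), inherits(spec, "vf_permutation_spec"))
  if (cohort$interval_multiplier != 1L)
    stop("derive_permutation: permutations are derived from a core series")
  k <- spec$tests_per_visit
  if (k > cohort$tests_per_visit)
    stop("derive_permutation: tests_per_visit exceeds the core's")
  vi <- seq(1L, dim(cohort$md)[2], by = spec$interval_multiplier)
  out <- cohort
  out$md <- cohort$md[, vi, seq_len(k), drop = FALSE]
  out$reliable <- cohort$reliable[, vi, seq_len(k), drop = FALSE]
  out$tests_per_visit <- k
  out$interval_multiplier <- spec$interval_multiplier
  out$visit_times <- cohort$visit_times[vi]
  out
}

#' Write a core series as a long-format CSV
#'
#' One row per (subject, visit, test): columns `subject_id`,
#' `visit_index`, `time`, `test_index`, `md_db`, `reliable` (0/1).
#'
#' @param cohort A `vf_cohort`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_core_csv <- function(cohort, path) {
  d <- dim(cohort$md)
  long <- data.frame(
    subject_id = rep(cohort$population$subject_id, times = d[2] * d[3]),
    visit_index = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time = rep(rep(cohort$visit_times, each = d[1]), times = d[3]),
    test_index = rep(seq_len(d[3]), each = d[1] * d[2]),
    md_db = as.vector(cohort$md),
    reliable = as.integer(as.vector(cohort$reliable)))
  long <- long[order(long$subject_id, long$visit_index, long$test_index), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
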