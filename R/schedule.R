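#' Testing schedules
#'
#' A schedule defines the visit grid of the core dataset: the long-term
#' plan has 81 visits at 3-monthly intervals over 20 years (times in
#' years, 0, 0.25, ..., 20); the short-term plan has 28 daily visits
#' (times in days, 0, 1, ..., 27). Four tests are administered per visit
#' in the core dataset; sparser conditions are derived by subsetting, see
#' [derive_permutation()].
#'
#' @param family `"long_term"` or `"short_term"`.
#' @param visit_times Optional numeric vector overriding the default
#'   visit grid; must start at 0 and be strictly increasing. Units are
#'   years for `long_term` and days for `short_term`.
#' @param tests_per_visit Number of tests per visit in the core dataset
#'   (default 4).
#'
#' @return An object of class `vf_schedule`: a list with fields
#'   `family`, `visit_times`, `time_unit` (`"years"` or `"days"`) and
#'   `tests_per_visit`.
#' @examples
#' vf_schedule("short_term")
#' @export
vf_schedule <- function(family = c("long_term", "short_term"),
                        visit_times = NULL, tests_per_visit = 4L) {
  family <- match.arg(family)
  if (is.null(visit_times))
    visit_times <- if (family == "long_term") seq(0, 20, by = 0.25) else 0:27
  visit_times <- as.numeric(visit_times)
  if (length(visit_times) < 1L || visit_times[1] != 0)
    stop("vf_schedule: visit_times must start at 0")
  if (any(diff(visit_times) <= 0))
    stop("vf_schedule: visit_times must be strictly increasing")
  tests_per_visit <- as.integer(tests_per_visit)
  if (tests_per_visit < 1L) stop("vf_schedule: tests_per_visit must be >= 1")
  structure(list(family = family,
                 visit_times = visit_times,
                 time_unit = if (family == "long_term") "years" else "days",
                 tests_per_visit = tests_per_visit),
            class = "vf_schedule")
}

#' @export
print.vf_schedule <- function(x, ...) {
  cat(sprintf("Visual-field schedule '%s': %d visits at %s %g to %g, %d tests/visit\n",
              x$family, length(x$visit_times), x$time_unit,
              x$visit_times[1], x$visit_times[length(x$visit_times)],
              x$tests_per_visit))
  invisible(x)
}

#' Tests-per-visit by review-interval condition
#'
#' A permutation is one of the 12 derived testing conditions: `k` tests
#' per visit (1-4) at every `m`-th visit of the core grid (`m` in
#' {1, 2, 4}; 3-/6-/12-monthly for the long-term plan, daily/2-daily/
#' 4-daily for the short-term plan).
#'
#' @param tests_per_visit Number of tests retained per visit, 1-4.
#' @param interval_multiplier Visit subsampling factor, one of 1, 2, 4.
#'
#' @return An object of class `vf_permutation_spec`.
#' @examples
#' permutation_spec(2, 4)
#' @export
permutation_spec <- function(tests_per_visit, interval_multiplier) {
  tests_per_visit <- as.integer(tests_per_visit)
  interval_multiplier <- as.integer(interval_multiplier)
  if (!(tests_per_visit %in% 1:4))
    stop("permutation_spec: tests_per_visit must be in 1..4")
  if (!(interval_multiplier %in% c(1L, 2L, 4L)))
    stop("permutation_spec: interval_multiplier must be 1, 2 or 4")
  structure(list(tests_per_visit = tests_per_visit,
                 interval_multiplier = interval_multiplier),
            class = "vf_permutation_spec")
}

#' All 12 testing permutations
#'
#' @return A list of [permutation_spec()] objects covering
#'   tests-per-visit 1-4 crossed with interval multipliers 1, 2, 4.
#' @export
all_permutations <- function() {
  grid <- expand.grid(k = 1:4, m = c(1L, 2L, 4L))
  lapply(seq_len(nrow(grid)),
         function(i) permutation_spec(grid$k[i], grid$m[i]))
}

# human-readable review-interval label for a permutation under a family
interval_label <- function(family, m) {
  if (family == "long_term")
    c(`1` = "3-monthly", `2` = "6-monthly", `4` = "12-monthly")[[as.character(m)]]
  else
    c(`1` = "daily", `2` = "every 2 days", `4` = "every 4 days")[[as.character(m)]]
}
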