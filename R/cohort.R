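outcome_cols <- c(tcv = "tcv", tgv = "tgv", tcr = "tcr", tgr = "tgr")

#' Summarize one outcome of a critical-times table
#'
#' Median and quartiles over detected subjects (censored subjects are
#' excluded from the quantiles but count in the denominator of the
#' cumulative detection proportion). Quantiles use linear interpolation
#' between order statistics (R type 7).
#'
#' @param ct A `vf_critical_times` data frame for a single permutation.
#' @param outcome One of `"tcv"`, `"tgv"`, `"tcr"`, `"tgr"`.
#'
#' @return An object of class `vf_permutation_summary`: a list with
#'   `outcome`, `tests_per_visit`, `interval`, `n_total`, `n_detected`,
#'   `median`, `q25`, `q75` (all `NA` when nothing is detected) and
#'   `detection_curve`, a `data.frame` (`time`, `proportion`) giving the
#'   non-decreasing proportion of all subjects detected by each visit
#'   time.
#' @export
summarize_critical_times <- function(ct, outcome = c("tcv", "tgv", "tcr", "tgr")) {
  outcome <- match.arg(outcome)
  x <- ct[[outcome]]
  times <- attr(ct, "visit_times")
  if (length(unique(ct$interval_multiplier)) > 1L ||
      length(unique(ct$tests_per_visit)) > 1L)
    stop("summarize_critical_times: ct must hold a single permutation; ",
         "see critical_time_table() for stacked tables")
  grid <- times
  det <- x[!is.na(x)]
  qs <- if (length(det)) stats::quantile(det, c(0.5, 0.25, 0.75),
                                         names = FALSE, type = 7)
        else rep(NA_real_, 3)
  curve <- data.frame(time = grid,
                      proportion = vapply(grid, function(tt)
                        mean(!is.na(x) & x <= tt), numeric(1)))
  structure(list(outcome = outcome,
                 tests_per_visit = unique(ct$tests_per_visit),
                 interval = unique(ct$interval),
                 n_total = nrow(ct),
                 n_detected = length(det),
                 median = qs[1], q25 = qs[2], q75 = qs[3],
                 detection_curve = curve),
            class = "vf_permutation_summary")
}

#' @export
print.vf_permutation_summary <- function(x, ...) {
  cat(sprintf("%s, %d test(s)/visit, %s: %d/%d detected",
              toupper(x$outcome), x$tests_per_visit, x$interval,
              x$n_detected, x$n_total))
  if (x$n_detected > 0)
    cat(sprintf(", median %g (%g, %g)", x$median, x$q25, x$q75))
  cat("\n")
  invisible(x)
}

#' Cumulative detection curves for all permutations
#'
#' @param ct A stacked `vf_critical_times` data frame
#'   ([compute_critical_times_all()]).
#' @param outcome One of `"tcv"`, `"tgv"`, `"tcr"`, `"tgr"`.
#'
#' @return A `data.frame` with columns `outcome`, `tests_per_visit`,
#'   `interval`, `time`, `proportion`.
#' @export
detection_curves <- function(ct, outcome = c("tcv", "tgv", "tcr", "tgr")) {
  outcome <- match.arg(outcome)
  parts <- lapply(split(ct, list(ct$tests_per_visit, ct$interval_multiplier)),
                  function(d) {
    s <- summarize_with_attrs(d, ct, outcome)
    cbind(outcome = outcome,
          tests_per_visit = s$tests_per_visit,
          interval = s$interval,
          s$detection_curve)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# re-attach stacked-table attributes to a single-permutation slice
summarize_with_attrs <- function(slice, ct, outcome) {
  m <- unique(slice$interval_multiplier)
  full <- attr(ct, "visit_times")
  attr(slice, "visit_times") <- full[seq(1L, length(full), by = m)]
  class(slice) <- class(ct)
  summarize_critical_times(slice, outcome)
}

#' Compare critical times across groups (Kruskal-Wallis)
#'
#' Nonparametric rank test of the detected critical times across the
#' levels of a grouping factor (number of tests per visit, or review
#' interval). Censored subjects are excluded.
#'
#' @param ct A stacked `vf_critical_times` data frame.
#' @param outcome One of `"tcv"`, `"tgv"`, `"tcr"`, `"tgr"`.
#' @param by Grouping variable: `"tests_per_visit"` or `"interval"`.
#'
#' @return A list with `statistic` (Kruskal-Wallis H), `df`, `p_value`
#'   and `groups` (per-group detected counts).
#' @export
compare_groups <- function(ct, outcome = c("tcv", "tgv", "tcr", "tgr"),
                           by = c("tests_per_visit", "interval")) {
  outcome <- match.arg(outcome)
  by <- match.arg(by)
  g <- if (by == "interval") ct$interval_multiplier else ct[[by]]
  x <- ct[[outcome]]
  keep <- !is.na(x)
  x <- x[keep]; g <- factor(g[keep])
  if (nlevels(g) < 2L)
    stop("compare_groups: need at least two groups")
  if (any(table(g) < 1L))
    stop("compare_groups: every group needs at least one detected subject")
  kw <- stats::kruskal.test(x, g)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, groups = table(g))
}

#' Difference between estimates at the critical time and the ground truth
#'
#' Restricted to subjects with both the consecutive-criterion and the
#' ground-truth critical time detected (TcV and TgV pairs for
#' variability, TcR and TgR pairs for reliability), the difference is
#' the running estimate at the consecutive critical time minus the
#' subject's true parameter. A one-sample t-test against zero quantifies
#' systematic bias.
#'
#' @param ct A `vf_critical_times` data frame (one permutation or
#'   stacked; pass a single permutation's rows to mirror per-condition
#'   analyses).
#' @param quantity `"variability"` (dB) or `"reliability"` (proportion).
#'
#' @return A list with `quantity`, `n`, `differences`, `median`, `q25`,
#'   `q75`, `range`, `t_statistic` and `p_value` (t-test results are
#'   `NA` when degenerate, e.g. all differences identical). Empty
#'   filtered sets return `n = 0` with `NA` summaries.
#' @export
difference_from_truth <- function(ct, quantity = c("variability", "reliability")) {
  quantity <- match.arg(quantity)
  if (quantity == "variability") {
    keep <- !is.na(ct$tcv) & !is.na(ct$tgv)
    d <- ct$diff_var_db[keep]
  } else {
    keep <- !is.na(ct$tcr) & !is.na(ct$tgr)
    d <- ct$diff_rel[keep]
  }
  if (length(d) == 0L)
    return(list(quantity = quantity, n = 0L, differences = numeric(0),
                median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                range = c(NA_real_, NA_real_),
                t_statistic = NA_real_, p_value = NA_real_))
  tt <- tryCatch(stats::t.test(d, mu = 0),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  qs <- stats::quantile(d, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  list(quantity = quantity, n = length(d), differences = d,
       median = qs[1], q25 = qs[2], q75 = qs[3], range = range(d),
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Univariable regressions of critical time on baseline parameters
#'
#' One simple ordinary-least-squares regression per baseline predictor
#' (`md0_db`, `slope_db_per_year`, `sigma_db`, `reliability`) of the
#' detected critical times on that predictor, pooled across the supplied
#' permutations. Per-predictor coefficients of determination from simple
#' regressions are summable across predictors, which a multivariable fit
#' would not provide.
#'
#' @param ct A `vf_critical_times` data frame (typically stacked across
#'   the 12 permutations of a schedule family).
#' @param population The `vf_population` the cohort was simulated from.
#' @param outcome One of `"tcv"`, `"tgv"`, `"tcr"`, `"tgr"`.
#'
#' @return A `data.frame` with one row per predictor: `outcome`,
#'   `predictor`, `coefficient`, `std_error`, `p_value`, `r_squared`,
#'   `n`, `degenerate` (`TRUE` and `NA` statistics when the predictor
#'   has zero variance or fewer than 3 detected subjects).
#' @export
regress_predictors <- function(ct, population,
                               outcome = c("tcv", "tgv", "tcr", "tgr")) {
  outcome <- match.arg(outcome)
  preds <- c("md0_db", "slope_db_per_year", "sigma_db", "reliability")
  i <- match(ct$subject_id, population$subject_id)
  y <- ct[[outcome]]
  keep <- !is.na(y)
  rows <- lapply(preds, function(p) {
    x <- population[[p]][i][keep]
    yy <- y[keep]
    if (length(yy) < 3L || stats::var(x) == 0) {
      return(data.frame(outcome = outcome, predictor = p,
                        coefficient = NA_real_, std_error = NA_real_,
                        p_value = NA_real_, r_squared = NA_real_,
                        n = length(yy), degenerate = TRUE))
    }
    if (stats::var(yy) == 0) {
      # constant outcome: flat fit, nothing explained
      return(data.frame(outcome = outcome, predictor = p,
                        coefficient = 0, std_error = NA_real_,
                        p_value = NA_real_, r_squared = 0,
                        n = length(yy), degenerate = FALSE))
    }
    f <- stats::lm(yy ~ x)
    s <- summary(f)
    co <- s$coefficients
    data.frame(outcome = outcome, predictor = p,
               coefficient = co[2, 1], std_error = co[2, 2],
               p_value = co[2, 4], r_squared = s$r.squared,
               n = length(yy), degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median (IQR) table of critical times by interval and tests per visit
#'
#' Builds the familiar summary table shape for one outcome: one row per
#' review interval, one column per tests-per-visit condition, each cell
#' `"median (q25, q75)"` over detected subjects, plus Kruskal-Wallis
#' p-values across tests-per-visit (per row) and across intervals (per
#' column).
#'
#' @param ct A stacked `vf_critical_times` data frame.
#' @param outcome One of `"tcv"`, `"tgv"`, `"tcr"`, `"tgr"`.
#' @param digits Rounding for the printed cells (default 2).
#'
#' @return A `data.frame` with columns `interval`, `k1`...`k4`,
#'   `p_by_tests`; final row `p_by_interval` holds the per-column
#'   interval comparisons.
#' @export
critical_time_table <- function(ct, outcome = c("tcv", "tgv", "tcr", "tgr"),
                                digits = 2) {
  outcome <- match.arg(outcome)
  ms <- sort(unique(ct$interval_multiplier))
  ks <- sort(unique(ct$tests_per_visit))
  cell <- function(d) {
    x <- d[[outcome]]
    x <- x[!is.na(x)]
    if (!length(x)) return("-")
    q <- round(stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7),
               digits)
    sprintf("%g (%g, %g)", q[1], q[2], q[3])
  }
  fmt_p <- function(p) if (is.na(p)) "-" else if (p < 1e-4) "<0.0001"
                       else sprintf("%.4f", p)
  rows <- lapply(ms, function(m) {
    d_m <- ct[ct$interval_multiplier == m, ]
    cells <- vapply(ks, function(k)
      cell(d_m[d_m$tests_per_visit == k, ]), character(1))
    p <- tryCatch(compare_groups(d_m, outcome, "tests_per_visit")$p_value,
                  error = function(e) NA_real_)
    out <- data.frame(interval = unique(d_m$interval), t(cells),
                      p_by_tests = fmt_p(p))
    names(out)[2:(1 + length(ks))] <- paste0("k", ks)
    out
  })
  tab <- do.call(rbind, rows)
  p_int <- vapply(ks, function(k) {
    d_k <- ct[ct$tests_per_visit == k, ]
    fmt_p(tryCatch(compare_groups(d_k, outcome, "interval")$p_value,
                   error = function(e) NA_real_))
  }, character(1))
  tab[nrow(tab) + 1L, ] <- c("p_by_interval", p_int, "-")
  rownames(tab) <- NULL
  tab
}
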