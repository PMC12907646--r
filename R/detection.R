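#' Probability of detecting a signal with a single test
#'
#' One-sided normal detection: the probability that a single test
#' detects a true mean-deviation difference of `signal` dB against
#' test-retest noise of SD `variability` dB is the standard normal CDF
#' evaluated at the signal-to-noise ratio,
#' \eqn{\Phi(\mathrm{signal}/\sigma)}.
#'
#' @param signal True difference to detect, in dB (e.g. 0.8).
#' @param variability Intrinsic variability (noise SD), dB, > 0.
#'
#' @return Detection probability. Vectorized over both arguments.
#' @examples
#' single_test_detection(0.8, 0.5)  # 0.9452
#' @export
single_test_detection <- function(signal, variability) {
  if (any(!is.finite(variability)) || any(variability <= 0))
    stop("single_test_detection: variability must be > 0")
  stats::pnorm(signal / variability)
}

#' Probability of at least one detection among n tests
#'
#' Under independent repeats with per-test detection probability
#' `p_single`, the probability that at least one of `n` tests detects is
#' `1 - (1 - p_single)^n`.
#'
#' @param p_single Per-test detection probability in `[0, 1]`.
#' @param n Number of tests per visit, >= 1.
#'
#' @return Detection probability. Vectorized.
#' @examples
#' at_least_one_detection(0.5, 2)  # 0.75
#' @export
at_least_one_detection <- function(p_single, n) {
  if (any(p_single < 0 | p_single > 1))
    stop("at_least_one_detection: p_single must be in [0, 1]")
  if (any(n < 1)) stop("at_least_one_detection: n must be >= 1")
  1 - (1 - p_single)^n
}

#' Detection-probability grid over variability and tests per visit
#'
#' Maps the probability of detecting a fixed mean-deviation difference
#' on at least one test of a visit, over a grid of intrinsic variability
#' levels and 1..`max_tests` tests per visit. This is the signal-to-noise
#' framework for tailoring test intensity to a patient's variability.
#'
#' @param signal Difference to detect, dB (default 0.8).
#' @param variability_levels Variability levels (noise SD), dB, all > 0.
#' @param max_tests Maximum number of tests per visit (default 4).
#'
#' @return An object of class `vf_detection_grid`: a list with `signal`,
#'   `variability_levels`, `snr` (`signal / variability`), `p_single`,
#'   and `p_at_least_one`, a matrix with one row per variability level
#'   and one column per tests-per-visit count.
#' @examples
#' build_detection_grid()
#' @export
build_detection_grid <- function(signal = 0.8,
                                 variability_levels = c(0.5, 1, 1.5, 2, 2.5),
                                 max_tests = 4L) {
  max_tests <- as.integer(max_tests)
  if (max_tests < 1L) stop("build_detection_grid: max_tests must be >= 1")
  p1 <- single_test_detection(signal, variability_levels)
  grid <- outer(p1, seq_len(max_tests), at_least_one_detection)
  dimnames(grid) <- list(variability = as.character(variability_levels),
                         tests = as.character(seq_len(max_tests)))
  structure(list(signal = signal,
                 variability_levels = variability_levels,
                 snr = signal / variability_levels,
                 p_single = p1,
                 p_at_least_one = grid),
            class = "vf_detection_grid")
}

#' @export
print.vf_detection_grid <- function(x, ...) {
  cat(sprintf("Detection probability of a %g dB difference on >= 1 test per visit\n",
              x$signal))
  tab <- cbind(snr = round(x$snr, 3), round(x$p_at_least_one, 4))
  colnames(tab) <- c("SNR", paste0(colnames(x$p_at_least_one), " test(s)"))
  print(tab)
  invisible(x)
}

#' Write a detection grid as CSV
#'
#' Rows are variability levels, columns the tests-per-visit counts,
#' preceded by the signal-to-noise ratio.
#'
#' @param grid A `vf_detection_grid`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_detection_grid_csv <- function(grid, path) {
  d <- data.frame(variability_db = grid$variability_levels,
                  snr = grid$snr,
                  grid$p_at_least_one, check.names = FALSE)
  names(d)[-(1:2)] <- paste0("tests_", colnames(grid$p_at_least_one))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
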