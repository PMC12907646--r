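# Independent naive re-scan implementations of the rolling-window rules,
# used as oracles against the package's vectorized scanners. They compress
# the defined estimates and re-examine every triplet from scratch.

oracle_consecutive <- function(times, estimates, tolerance = 0.05) {
  idx <- which(!is.na(estimates))
  if (length(idx) >= 3) {
    for (j in 3:length(idx)) {
      trip <- estimates[idx[(j - 2):j]]
      if (max(trip) - min(trip) <= tolerance * mean(trip))
        return(times[idx[j]])
    }
  }
  NA_real_
}

oracle_ground_truth <- function(times, estimates, truth, tolerance = 0.05) {
  idx <- which(!is.na(estimates))
  if (length(idx) >= 3) {
    for (j in 3:length(idx)) {
      trip <- estimates[idx[(j - 2):j]]
      if (all(abs(trip - truth) <= tolerance * truth))
        return(times[idx[j]])
    }
  }
  NA_real_
}

# random running-estimate series with gaps (NA visits)
random_gapped_series <- function(len, p_gap = 0.3, level = 1.5, wobble = 0.1) {
  e <- level * exp(cumsum(stats::rnorm(len, 0, wobble)) / sqrt(seq_len(len)))
  e[stats::runif(len) < p_gap] <- NA
  e
}

# population with known seed for module tests
test_population <- function(n, seed = 1) {
  set.seed(seed)
  sample_population(n)
}

# population with fixed (non-random) parameters
make_fixed_population <- function(md0, slope, sigma, reliability) {
  out <- data.frame(subject_id = seq_along(md0), md0_db = md0,
                    slope_db_per_year = slope, sigma_db = sigma,
                    reliability = reliability)
  class(out) <- c("vf_population", "data.frame")
  out
}
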