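#' Distribution configuration for the simulated population
#'
#' Bundles the hyperparameters of the four per-subject parameter
#' distributions: baseline mean deviation (normal), progression rate
#' (Azzalini skew-normal), intrinsic variability (lognormal, so that
#' sampled values stay positive) and intrinsic reliability (beta,
#' linearly rescaled onto `[rel_low, rel_high]`).
#'
#' The defaults describe a predominantly early-glaucoma population with a
#' wide range of progression rates (long left tail towards fast
#' progressors) and a reliability distribution biased towards highly
#' reliable subjects with a left tail of poorly reliable ones.
#'
#' @param md_mean,md_sd Mean and SD (dB) of baseline mean deviation.
#' @param slope_location,slope_scale,slope_skew Location (dB/year), scale
#'   (dB/year) and shape of the skew-normal progression-rate distribution.
#' @param var_log_mean,var_log_sigma Mean and SD of log intrinsic
#'   variability (log-dB scale); the sampled variability is
#'   `exp(Normal(var_log_mean, var_log_sigma))`.
#' @param rel_low,rel_high Bounds of the reliability range (proportions).
#' @param rel_alpha,rel_beta Shape parameters of the underlying beta
#'   distribution for reliability.
#'
#' @return An object of class `vf_distribution_config` (a validated list).
#' @examples
#' cfg <- distribution_config()
#' cfg
#' @export
distribution_config <- function(md_mean = -4, md_sd = 2,
                                slope_location = -0.05, slope_scale = 0.8,
                                slope_skew = -2,
                                var_log_mean = 0.5, var_log_sigma = 0.4,
                                rel_low = 0.5, rel_high = 0.99,
                                rel_alpha = 9, rel_beta = 1.5) {
  cfg <- list(md_mean = md_mean, md_sd = md_sd,
              slope_location = slope_location, slope_scale = slope_scale,
              slope_skew = slope_skew,
              var_log_mean = var_log_mean, var_log_sigma = var_log_sigma,
              rel_low = rel_low, rel_high = rel_high,
              rel_alpha = rel_alpha, rel_beta = rel_beta)
  bad <- !vapply(cfg, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                 logical(1))
  if (any(bad))
    stop("distribution_config: non-numeric or non-scalar fields: ",
         paste(names(cfg)[bad], collapse = ", "))
  if (md_sd <= 0) stop("distribution_config: md_sd must be > 0")
  if (slope_scale <= 0) stop("distribution_config: slope_scale must be > 0")
  if (var_log_sigma <= 0) stop("distribution_config: var_log_sigma must be > 0")
  if (!(rel_low >= 0 && rel_low < rel_high && rel_high <= 1))
    stop("distribution_config: need 0 <= rel_low < rel_high <= 1")
  if (rel_alpha <= 0 || rel_beta <= 0)
    stop("distribution_config: rel_alpha and rel_beta must be > 0")
  structure(cfg, class = "vf_distribution_config")
}

#' @export
print.vf_distribution_config <- function(x, ...) {
  cat("Visual-field population distributions\n")
  cat(sprintf("  baseline MD : Normal(%g dB, sd %g dB)\n", x$md_mean, x$md_sd))
  cat(sprintf("  progression : SkewNormal(loc %g, scale %g, shape %g) dB/yr\n",
              x$slope_location, x$slope_scale, x$slope_skew))
  cat(sprintf("  variability : exp(Normal(%g, %g)) dB\n",
              x$var_log_mean, x$var_log_sigma))
  cat(sprintf("  reliability : %g + %g * Beta(%g, %g)\n",
              x$rel_low, x$rel_high - x$rel_low, x$rel_alpha, x$rel_beta))
  invisible(x)
}

#' Sample from an Azzalini skew-normal distribution
#'
#' Draws from SN(location, scale, shape) using the two-normal delta
#' representation: with \eqn{\delta = \alpha / \sqrt{1 + \alpha^2}} and
#' independent standard normals \eqn{Z_0, Z_1},
#' \eqn{X = \xi + \omega(\delta |Z_0| + \sqrt{1-\delta^2} Z_1)} is
#' skew-normal with shape \eqn{\alpha}. With `skew = 0` this reduces to
#' `Normal(location, scale)`.
#'
#' @param n Number of draws (non-negative integer).
#' @param location Location parameter \eqn{\xi}.
#' @param scale Scale parameter \eqn{\omega > 0}.
#' @param skew Shape parameter \eqn{\alpha} (dimensionless).
#'
#' @return Numeric vector of length `n`. The population mean is
#'   `location + scale * delta * sqrt(2/pi)`.
#' @examples
#' set.seed(1)
#' mean(sample_skew_normal(1e4, 0, 1, 0))  # ~ 0
#' @export
sample_skew_normal <- function(n, location = 0, scale = 1, skew = 0) {
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("sample_skew_normal: n must be a non-negative count")
  if (!is.finite(scale) || scale <= 0)
    stop("sample_skew_normal: scale must be > 0")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  delta <- skew / sqrt(1 + skew^2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  location + scale * (delta * z0 + sqrt(1 - delta^2) * z1)
}

#' Sample a simulated population of perimetry subjects
#'
#' Draws `n` subjects, each with a ground-truth parameter quadruple:
#' baseline mean deviation `md0_db`, progression rate
#' `slope_db_per_year`, intrinsic variability `sigma_db` (always
#' positive) and intrinsic reliability `reliability` (within
#' `[rel_low, rel_high]`). Parameters are sampled mutually independently.
#'
#' @param n Number of subjects (non-negative).
#' @param config A [distribution_config()] object.
#'
#' @return A `data.frame` of class `vf_population` with columns
#'   `subject_id`, `md0_db`, `slope_db_per_year`, `sigma_db`,
#'   `reliability`.
#' @examples
#' set.seed(1)
#' pop <- sample_population(5)
#' pop
#' @export
sample_population <- function(n, config = distribution_config()) {
  if (!inherits(config, "vf_distribution_config"))
    config <- do.call(distribution_config, as.list(config))
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("sample_population: n must be a non-negative count")
  n <- as.integer(n)
  # fixed draw order: md0, slope, sigma, reliability (reproducibility contract)
  md0 <- stats::rnorm(n, config$md_mean, config$md_sd)
  slope <- sample_skew_normal(n, config$slope_location, config$slope_scale,
                              config$slope_skew)
  sigma <- exp(stats::rnorm(n, config$var_log_mean, config$var_log_sigma))
  reliability <- config$rel_low +
    (config$rel_high - config$rel_low) * stats::rbeta(n, config$rel_alpha,
                                                      config$rel_beta)
  out <- data.frame(subject_id = seq_len(n),
                    md0_db = md0,
                    slope_db_per_year = slope,
                    sigma_db = sigma,
                    reliability = reliability)
  class(out) <- c("vf_population", "data.frame")
  attr(out, "config") <- config
  out
}

#' Summarize the empirical parameter distributions of a population
#'
#' @param population A `vf_population` data frame from
#'   [sample_population()].
#'
#' @return A `data.frame` with one row per parameter (`md0_db`,
#'   `slope_db_per_year`, `sigma_db`, `reliability`) and columns
#'   `median`, `q25`, `q75` (sample quantiles, linear interpolation
#'   between order statistics).
#' @export
summarize_population <- function(population) {
  if (nrow(population) == 0L)
    stop("summarize_population: empty population")
  vars <- c("md0_db", "slope_db_per_year", "sigma_db", "reliability")
  qs <- t(vapply(vars, function(v)
    stats::quantile(population[[v]], c(0.5, 0.25, 0.75), names = FALSE, type = 7),
    numeric(3)))
  data.frame(parameter = vars, median = qs[, 1], q25 = qs[, 2], q75 = qs[, 3],
             row.names = NULL)
}
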