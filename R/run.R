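#' Default run configuration
#'
#' The default configuration reproduces the study conditions: 100 000
#' subjects, both schedule families, all 12 permutations, 5% rolling
#' window tolerance.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param schedule_family `"long_term"`, `"short_term"` or `"both"`.
#' @param tolerance Rolling-window tolerance in (0, 1); 0.05 by default,
#'   0.10 for the laxer sensitivity analysis.
#' @param distribution A [distribution_config()] (or a named list of its
#'   fields).
#' @param permutations List of [permutation_spec()]s, or of
#'   `c(tests_per_visit, interval_multiplier)` pairs; default all 12.
#' @param seed Integer master seed.
#' @param output_dir Directory for artifacts.
#'
#' @return A list of class `vf_run_config`.
#' @export
default_run_config <- function(n_subjects = 100000L,
                               schedule_family = "both",
                               tolerance = 0.05,
                               distribution = distribution_config(),
                               permutations = all_permutations(),
                               seed = 1L,
                               output_dir = "perisim_output") {
  cfg <- list(n_subjects = n_subjects, schedule_family = schedule_family,
              tolerance = tolerance, distribution = distribution,
              permutations = permutations, seed = seed,
              output_dir = output_dir)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  known <- c("n_subjects", "schedule_family", "tolerance", "distribution",
             "permutations", "seed", "output_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("run config: unknown keys: ", paste(extra, collapse = ", "))
  defaults <- list(n_subjects = 100000L, schedule_family = "both",
                   tolerance = 0.05, distribution = distribution_config(),
                   permutations = all_permutations(), seed = 1L,
                   output_dir = "perisim_output")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  bad <- character(0)
  if (!(is.numeric(cfg$n_subjects) && length(cfg$n_subjects) == 1L &&
        !is.na(cfg$n_subjects) && cfg$n_subjects >= 1))
    bad <- c(bad, "n_subjects")
  if (!(cfg$schedule_family %in% c("long_term", "short_term", "both")))
    bad <- c(bad, "schedule_family")
  if (!(is.numeric(cfg$tolerance) && length(cfg$tolerance) == 1L &&
        cfg$tolerance > 0 && cfg$tolerance < 1))
    bad <- c(bad, "tolerance")
  if (!(is.numeric(cfg$seed) && length(cfg$seed) == 1L && !is.na(cfg$seed)))
    bad <- c(bad, "seed")
  if (length(bad))
    stop("run config: invalid values for: ", paste(bad, collapse = ", "))
  if (!inherits(cfg$distribution, "vf_distribution_config"))
    cfg$distribution <- do.call(distribution_config, as.list(cfg$distribution))
  cfg$permutations <- lapply(cfg$permutations, function(p) {
    if (inherits(p, "vf_permutation_spec")) p
    else permutation_spec(p[[1]], p[[2]])
  })
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "vf_run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Missing keys take the default (study) values; an empty file yields the
#' full default configuration. Keys mirror the arguments of
#' [default_run_config()]; `distribution` is a mapping of
#' [distribution_config()] fields and `permutations` a list of
#' `[tests_per_visit, interval_multiplier]` pairs.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `vf_run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.null(cfg$distribution)) cfg$distribution <- as.list(cfg$distribution)
  if (!is.null(cfg$permutations) && is.matrix(cfg$permutations))
    cfg$permutations <- asplit(cfg$permutations, 1)
  validate_run_config(cfg)
}

#' Read a critical-times CSV back as a `vf_critical_times` table
#'
#' Restores the class and schedule attributes of a critical-times table
#' written by [run_experiment()], so the cohort summaries
#' ([critical_time_table()], [detection_curves()], ...) can be re-run
#' from the CSV without re-simulation.
#'
#' @param path Path to a `critical_times_<family>.csv`.
#' @param family `"long_term"` or `"short_term"`; by default parsed from
#'   the file name.
#' @param tolerance The tolerance the table was computed with (attribute
#'   only; default 0.05).
#' @return A `vf_critical_times` data frame.
#' @export
read_critical_times_csv <- function(path, family = NULL, tolerance = 0.05) {
  if (is.null(family)) {
    family <- if (grepl("short_term", basename(path))) "short_term"
              else if (grepl("long_term", basename(path))) "long_term"
              else stop("read_critical_times_csv: cannot infer family from ",
                        basename(path), "; pass family=")
  }
  out <- utils::read.csv(path)
  sched <- vf_schedule(family)
  class(out) <- c("vf_critical_times", "data.frame")
  attr(out, "tolerance") <- tolerance
  attr(out, "family") <- family
  attr(out, "time_unit") <- sched$time_unit
  attr(out, "visit_times") <- sched$visit_times
  out
}

#' Run a full simulation experiment and write its artifacts
#'
#' Samples the population, simulates the core series for the requested
#' schedule families, derives all permutations, computes critical times,
#' and writes: the population table, per-family critical-times tables,
#' median (IQR) summary tables per outcome, cumulative detection curves,
#' difference-from-truth summaries, baseline-predictor regressions, the
#' detection-probability grid, and a JSON manifest recording the
#' configuration, seed and row counts. Identical configuration and seed
#' give byte-identical outputs.
#'
#' @param config A `vf_run_config` ([default_run_config()],
#'   [load_config()]).
#' @param quiet Suppress progress messages (default `FALSE`).
#'
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_experiment <- function(config = default_run_config(), quiet = FALSE) {
  config <- validate_run_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("run_experiment: cannot create output_dir: ", out)
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)
  say("seed %d | sampling %d subjects", config$seed, config$n_subjects)
  pop <- sample_population(config$n_subjects, config$distribution)
  files <- character(0)
  wr <- function(d, name) {
    p <- file.path(out, name)
    utils::write.csv(d, p, row.names = FALSE)
    files <<- c(files, name)
    p
  }
  wr(as.data.frame(pop), "population.csv")
  wr(summarize_population(pop), "population_summary.csv")
  families <- if (config$schedule_family == "both")
    c("long_term", "short_term") else config$schedule_family
  counts <- list(n_subjects = nrow(pop))
  for (fam in families) {
    say("simulating %s core series", fam)
    core <- simulate_core(pop, vf_schedule(fam))
    ct <- compute_critical_times_all(core, config$tolerance,
                                     config$permutations)
    wr(as.data.frame(ct), sprintf("critical_times_%s.csv", fam))
    cens <- stats::aggregate(cbind(tcv, tgv, tcr, tgr) ~
                               tests_per_visit + interval, data = ct,
                             FUN = function(x) sum(is.na(x)),
                             na.action = stats::na.pass)
    say("%s censored counts by permutation written", fam)
    wr(cens, sprintf("censored_%s.csv", fam))
    for (oc in names(outcome_cols)) {
      wr(critical_time_table(ct, oc), sprintf("table_%s_%s.csv", oc, fam))
      wr(detection_curves(ct, oc), sprintf("curves_%s_%s.csv", oc, fam))
    }
    diffs <- do.call(rbind, lapply(split(ct, list(ct$tests_per_visit,
                                                  ct$interval_multiplier)),
      function(d) {
        do.call(rbind, lapply(c("variability", "reliability"), function(qt) {
          s <- difference_from_truth(d, qt)
          data.frame(quantity = qt,
                     tests_per_visit = unique(d$tests_per_visit),
                     interval = unique(d$interval), n = s$n,
                     median = s$median, q25 = s$q25, q75 = s$q75,
                     min = s$range[1], max = s$range[2],
                     t_statistic = s$t_statistic, p_value = s$p_value)
        }))
      }))
    rownames(diffs) <- NULL
    wr(diffs, sprintf("differences_%s.csv", fam))
    reg <- do.call(rbind, lapply(names(outcome_cols), function(oc)
      regress_predictors(ct, pop, oc)))
    wr(reg, sprintf("regression_%s.csv", fam))
    counts[[paste0("critical_times_", fam)]] <- nrow(ct)
  }
  grid <- build_detection_grid()
  write_detection_grid_csv(grid, file.path(out, "detection_grid.csv"))
  files <- c(files, "detection_grid.csv")
  manifest <- list(
    package = "perisim",
    seed = config$seed,
    tolerance = config$tolerance,
    schedule_family = config$schedule_family,
    n_subjects = config$n_subjects,
    distribution = unclass(config$distribution),
    permutations = lapply(config$permutations,
                          function(p) c(p$tests_per_visit,
                                        p$interval_multiplier)),
    row_counts = counts,
    files = files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("wrote %d artifacts to %s", length(files) + 1L, out)
  invisible(manifest)
}
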