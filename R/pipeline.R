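# Orchestration: config-driven end-to-end runs of the three in-silico
# experiments (cue validity, SOA, stimulus complexity), file I/O, seeding.

#' Experiment configuration
#'
#' Expands a named experiment preset into its task-version list and bundles
#' the cohort description. The presets mirror the three study designs:
#' `exp1_validity` runs the basic task (all cues valid) and the modified
#' task (80 % valid / 20 % invalid); `exp2_soa` runs the task at cue-target
#' blank intervals of 50, 200 and 350 ms; `exp3_complexity` runs the
#' four-element and six-element stimulus alphabets.
#'
#' @param experiment One of `"exp1_validity"`, `"exp2_soa"`,
#'   `"exp3_complexity"`, `"custom"`.
#' @param n_subjects Cohort size, default 20.
#' @param seed Master seed for the whole run.
#' @param versions For `"custom"`: a named list of [awt_config()] objects.
#' @param mean_params Population-mean [observer_params()].
#' @param sd_extent,sd_slope Between-subject SDs (see [observer_cohort()]).
#' @return An object of class `awt_experiment_config`.
#' @export
experiment_config <- function(experiment = c("exp1_validity", "exp2_soa",
                                             "exp3_complexity", "custom"),
                              n_subjects = 20, seed = 1, versions = NULL,
                              mean_params = observer_params(),
                              sd_extent = 4, sd_slope = 0.3) {
  experiment <- match.arg(experiment)
  if (n_subjects < 2) abort("`n_subjects` must be at least 2.")
  versions <- switch(experiment,
    exp1_validity = list(
      basic = awt_config(cue_valid_fraction = 1),
      modified = awt_config(cue_valid_fraction = 0.8)
    ),
    exp2_soa = list(
      soa_050 = awt_config(soa_ms = 50),
      soa_200 = awt_config(soa_ms = 200),
      soa_350 = awt_config(soa_ms = 350)
    ),
    exp3_complexity = list(
      basic = awt_config(complexity = "basic4"),
      high_complexity = awt_config(complexity = "high6")
    ),
    custom = {
      if (is.null(versions) || is.null(names(versions)) ||
          !all(vapply(versions, inherits, logical(1), "awt_config"))) {
        abort("Custom experiments need a named list of awt_config versions.")
      }
      versions
    }
  )
  structure(
    list(experiment = experiment, versions = versions,
         n_subjects = n_subjects, seed = seed, mean_params = mean_params,
         sd_extent = sd_extent, sd_slope = sd_slope),
    class = "awt_experiment_config"
  )
}

#' @export
print.awt_experiment_config <- function(x, ...) {
  cat(sprintf("<awt_experiment_config> %s: %d subjects, %d versions (%s), seed %d\n",
              x$experiment, x$n_subjects, length(x$versions),
              paste(names(x$versions), collapse = ", "), x$seed))
  invisible(x)
}

#' Run one in-silico experiment end to end
#'
#' Draws the observer cohort, simulates every task version (each subject
#' completes all versions with version-specific sessions and noise
#' streams), scores accuracy, estimates per-subject thresholds (pooled
#' meridian classes and raw meridians), reconstructs attention-window
#' geometry from group-mean raw thresholds per version, runs the
#' version x meridian repeated-measures ANOVA, and summarises condition
#' effects as percent reductions. For the cue-validity experiment the
#' modified version is additionally split by cue validity and analysed with
#' the condition (valid vs invalid) x meridian ANOVA, the comparison the
#' paradigm is built around.
#'
#' @param config An [experiment_config()].
#' @return An object of class `awt_run` with elements `records`,
#'   `thresholds`, `thresholds_raw`, `summary`, `windows`, `anova_version`,
#'   `anova_validity` (exp1 only), `reductions` and `provenance`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "awt_experiment_config"))
  seeds <- child_seeds(config$seed, c("cohort", "versions"))
  cohort <- observer_cohort(config$n_subjects, seed = seeds[["cohort"]],
                            mean_params = config$mean_params,
                            sd_extent = config$sd_extent,
                            sd_slope = config$sd_slope)
  version_seeds <- child_seeds(seeds[["versions"]], names(config$versions))

  records <- map(names(config$versions), function(v) {
    rec <- simulate_cohort(cohort, config$versions[[v]],
                           seed = version_seeds[[v]])
    rec$version <- v
    rec
  }) |> list_rbind() |> relocate("version")

  grid <- config$versions[[1]]$separations_deg
  cells <- score_records(records, by = c("subject", "version"))
  thresholds <- estimate_thresholds(cells, separations = grid)
  cells_raw <- score_records(records, by = c("subject", "version"),
                             pool_diagonals = FALSE)
  thresholds_raw <- estimate_thresholds(cells_raw, separations = grid)

  summary <- thresholds |>
    group_by(.data$version, .data$meridian_class) |>
    summarise(mean_deg = mean(.data$threshold_deg),
              sd_deg = stats::sd(.data$threshold_deg),
              n_floor = sum(.data$censoring == "floor"),
              n_ceiling = sum(.data$censoring == "ceiling"),
              .groups = "drop")

  windows <- map(names(config$versions), function(v) {
    thr <- thresholds_raw |>
      filter(.data$version == v) |>
      group_by(.data$meridian_class) |>
      summarise(m = mean(.data$threshold_deg), .groups = "drop")
    aw <- build_attention_window(setNames(thr$m, thr$meridian_class))
    mutate(glance(aw), version = v, .before = 1)
  }) |> list_rbind()

  anova_version <- if (length(config$versions) >= 2) {
    rm_anova(thresholds, dv = "threshold_deg", subject = "subject",
             within = c("version", "meridian_class"))
  } else {
    NULL
  }

  anova_validity <- NULL
  validity_thresholds <- NULL
  if (config$experiment == "exp1_validity") {
    mod <- filter(records, .data$version == "modified")
    vcells <- score_records(mod, by = c("subject", "cue_validity"))
    validity_thresholds <- estimate_thresholds(vcells, separations = grid,
                                               on_missing = "drop")
    anova_validity <- rm_anova(validity_thresholds, dv = "threshold_deg",
                               subject = "subject",
                               within = c("cue_validity", "meridian_class"))
  }

  reductions <- run_reductions(config, thresholds, validity_thresholds)

  structure(
    list(
      config = config,
      records = records,
      thresholds = thresholds,
      thresholds_raw = thresholds_raw,
      validity_thresholds = validity_thresholds,
      summary = summary,
      windows = windows,
      anova_version = anova_version,
      anova_validity = anova_validity,
      reductions = reductions,
      provenance = list(
        experiment = config$experiment,
        seed = config$seed,
        config_hash = rlang::hash(config),
        n_subjects = config$n_subjects,
        versions = names(config$versions)
      )
    ),
    class = "awt_run"
  )
}

# condition-mean percent reductions appropriate to each preset
run_reductions <- function(config, thresholds, validity_thresholds) {
  version_mean <- function(v) {
    mean(thresholds$threshold_deg[thresholds$version == v])
  }
  switch(config$experiment,
    exp1_validity = {
      vm <- function(v) {
        mean(validity_thresholds$threshold_deg[
          validity_thresholds$cue_validity == v])
      }
      mutate(percent_reduction(vm("valid"), vm("invalid")),
             contrast = "valid vs invalid (modified task)", .before = 1)
    },
    exp2_soa = bind_rows(
      mutate(percent_reduction(version_mean("soa_200"),
                               version_mean("soa_050")),
             contrast = "SOA 200 ms vs 50 ms", .before = 1),
      mutate(percent_reduction(version_mean("soa_200"),
                               version_mean("soa_350")),
             contrast = "SOA 200 ms vs 350 ms", .before = 1)
    ),
    exp3_complexity = mutate(
      percent_reduction(version_mean("basic"),
                        version_mean("high_complexity")),
      contrast = "basic vs high complexity", .before = 1),
    {
      if (length(config$versions) >= 2) {
        ref <- names(config$versions)[1]
        map(names(config$versions)[-1], function(v) {
          mutate(percent_reduction(version_mean(ref), version_mean(v)),
                 contrast = paste(ref, "vs", v), .before = 1)
        }) |> list_rbind()
      } else {
        NULL
      }
    }
  )
}

#' @export
print.awt_run <- function(x, ...) {
  cat(sprintf("<awt_run> %s: %d subjects x %d versions, seed %d\n",
              x$provenance$experiment, x$provenance$n_subjects,
              length(x$provenance$versions), x$provenance$seed))
  cat("\nGroup thresholds (deg):\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  if (!is.null(x$anova_version)) {
    cat("\nVersion x meridian ANOVA:\n")
    print(x$anova_version)
  }
  if (!is.null(x$anova_validity)) {
    cat("\nCue validity x meridian ANOVA (modified task):\n")
    print(x$anova_validity)
  }
  if (!is.null(x$reductions)) {
    cat("\nPercent reductions:\n")
    print(as.data.frame(x$reductions), row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn run_experiment Per-subject threshold table of a run.
#' @param x An `awt_run` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.awt_run <- function(x, ...) {
  x$thresholds
}

#' @describeIn run_experiment One row per version: group means and window
#'   geometry.
#' @exportS3Method generics::glance
glance.awt_run <- function(x, ...) {
  x$windows
}

#' @describeIn run_experiment Group-mean threshold profile per version and
#'   meridian class, with standard-deviation ribbons.
#' @param object An `awt_run` object.
#' @exportS3Method ggplot2::autoplot
autoplot.awt_run <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$meridian_class, y = .data$mean_deg,
                 fill = .data$version)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_deg - .data$sd_deg,
                   ymax = .data$mean_deg + .data$sd_deg),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::labs(x = "meridian", y = "threshold separation (deg)",
                  fill = "task version") +
    ggplot2::theme_minimal()
}

#' Read and write trial-record tables
#'
#' Trial records travel as UTF-8 comma-separated text with a header row and
#' `.` as the decimal mark. Reading validates the schema and restores
#' column types; a missing column raises an error naming it.
#'
#' @param records A trial-record tibble.
#' @param path File path.
#' @return `write_trial_records()` returns `path` invisibly;
#'   `read_trial_records()` returns the tibble.
#' @export
write_trial_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

trial_record_cols <- function() {
  c("meridian", "separation_deg", "cue_validity", "cue_meridian",
    "cue_separation_deg", "soa_ms", "complexity", "stim_a", "stim_b",
    "target_count_a", "target_count_b", "reported_count_a",
    "reported_count_b", "correct")
}

#' @rdname write_trial_records
#' @export
read_trial_records <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(trial_record_cols(), names(out))
  if (length(missing) > 0) {
    abort(paste0("Trial-record file ", path, " is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  out
}

#' Read and write run reports
#'
#' Serialises the summary tables of an [run_experiment()] result (group
#' summaries, window geometry, effect tables, reductions, provenance) as
#' JSON. The trial records themselves are written separately with
#' [write_trial_records()]; every reported number is recomputable from
#' them.
#'
#' @param run An `awt_run` object.
#' @param path File path for the JSON report.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the report as a list of tibbles/values.
#' @export
write_report <- function(run, path) {
  stopifnot(inherits(run, "awt_run"))
  report <- list(
    schema = "awt_run_report/1",
    provenance = run$provenance,
    summary = run$summary,
    windows = run$windows,
    thresholds = run$thresholds,
    anova_version = if (!is.null(run$anova_version)) tidy(run$anova_version),
    anova_validity = if (!is.null(run$anova_validity)) tidy(run$anova_validity),
    reductions = run$reductions
  )
  jsonlite::write_json(report, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(report$schema, "awt_run_report/1")) {
    abort(paste0("File ", path, " is not an awt_run_report/1 document."))
  }
  for (nm in c("summary", "windows", "thresholds", "anova_version",
               "anova_validity", "reductions")) {
    if (!is.null(report[[nm]])) report[[nm]] <- as_tibble(report[[nm]])
  }
  report
}
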