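#' Default pipeline configuration
#'
#' All tunables of the end-to-end analysis, defaulting to the study
#' conditions: a 35-runner x 7-run cohort of >= 12 km runs; segmentation with
#' 1 km warmup discard, 10 km cap, 10 s smoothing, 1.8 m/s speed gate and
#' 100 m windows; the 5% quantile-change stability rule at 95% density
#' coverage; and a five-train/two-test crossover.
#'
#' @param n_runners,n_runs Cohort size.
#' @param cohort A [cohort_config()].
#' @param seed Master seed; every stage's randomness descends from it.
#' @param ... Overrides for the `segmentation`, `stability` or `crossover`
#'   sub-lists (each a named list).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_runners = 35, n_runs = 7,
                            cohort = cohort_config(), seed = 1, ...) {
  cfg <- list(
    n_runners = n_runners, n_runs = n_runs, cohort = cohort, seed = seed,
    input_dir = NULL,
    segmentation = list(min_speed = 1.8, window_m = 100, warmup_km = 1,
                        cap_km = 10, smooth_s = 10),
    stability = list(threshold = 5, variables = "all", sustained = FALSE,
                     include_sweep = FALSE),
    crossover = list(n_train = NULL)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  with(cfg$segmentation, stopifnot(min_speed > 0, window_m > 0,
                                   warmup_km > 0, cap_km > warmup_km))
  stopifnot(cfg$stability$threshold > 0)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields and the `segmentation` / `stability` / `crossover` sub-maps
#' override [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  top <- y[setdiff(names(y), c("segmentation", "stability", "crossover", "cohort"))]
  cohort <- if (!is.null(y$cohort)) do.call(cohort_config, y$cohort) else cohort_config()
  do.call(pipeline_config, c(top, list(cohort = cohort),
                             y[intersect(names(y),
                                         c("segmentation", "stability", "crossover"))]))
}

#' Run the full stability pipeline and write all result tables
#'
#' Orchestrates simulate -> segment -> stability -> crossover and writes a
#' reproducible artifact directory: per-condition characteristics
#' (`conditions_summary.csv`), the train/test enumeration audit
#' (`enumeration_audit.csv`), per-runner stability points
#' (`stability_points.csv`) and their cohort summary
#' (`stability_summary.csv`), crossover counts and correlation matrices
#' (`crossover_counts.csv`, `crossover_correlations.csv`), per-condition
#' multivariate density models (`models.json`), the resolved configuration
#' (`config.json`) and a run log (`log.txt`) recording seeds and any
#' covariance regularization events. When `config$input_dir` is set, CSV
#' streams are read from it instead of simulating.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return `out_dir`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("master seed: %d", config$seed))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(
      withCallingHandlers(expr, message = function(m) {
        note("[%s] %s", name, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }),
      error = function(e) abort(paste0(name, " stage failed: ",
                                       conditionMessage(e)))
    )
  }

  cohort <- stage("simulate", {
    if (!is.null(config$input_dir)) NULL else {
      note("simulating %d runners x %d runs", config$n_runners, config$n_runs)
      simulate_cohort(config$n_runners, config$n_runs, config$cohort,
                      seed = derive_seed(config$seed, 10L))
    }
  })

  seg <- stage("segmentation", {
    src <- if (!is.null(config$input_dir)) {
      if (!dir.exists(config$input_dir)) {
        stop("GPS/IMU input directory not found: ", config$input_dir)
      }
      streams <- read_cohort_csv(config$input_dir)
      do.call(segment_runs, c(list(streams$gps, streams$imu), config$segmentation))
    } else {
      do.call(segment_runs, c(list(cohort), config$segmentation))
    }
    src
  })
  readr::write_csv(summarize_conditions(seg),
                   file.path(out_dir, "conditions_summary.csv"))

  stab <- stage("stability", {
    n_runs_obs <- max(seg$records$run_id)
    readr::write_csv(split_counts(n_runs_obs),
                     file.path(out_dir, "enumeration_audit.csv"))
    scan <- stability_scan(seg, variables = config$stability$variables,
                           threshold = config$stability$threshold,
                           sustained = config$stability$sustained)
    readr::write_csv(scan, file.path(out_dir, "stability_points.csv"))
    summ <- suppressWarnings(stability_summary(scan))
    readr::write_csv(summ, file.path(out_dir, "stability_summary.csv"))
    if (isTRUE(config$stability$include_sweep)) {
      readr::write_csv(similarity_sweep(seg, variables = config$stability$variables),
                       file.path(out_dir, "similarity_sweep.csv"))
    }
    scan
  })

  stage("crossover", {
    xo <- crossover_counts(seg, variables = config$stability$variables,
                           seed = derive_seed(config$seed, 20L),
                           n_train = config$crossover$n_train)
    readr::write_csv(xo$counts, file.path(out_dir, "crossover_counts.csv"))
    readr::write_csv(crossover_correlations(xo),
                     file.path(out_dir, "crossover_correlations.csv"))
  })

  stage("models", {
    models <- list()
    for (rid in unique(seg$records$runner_id)) {
      rec <- dplyr::filter(seg$records, .data$runner_id == !!rid)
      for (cond in gait_conditions()) {
        x <- condition_records(rec, cond)
        if (nrow(x) < 7) next
        fit <- fit_gait_density(x, gait_variables())
        models[[paste(rid, cond, sep = ".")]] <- list(
          runner_id = rid, condition = cond, variables = fit$variables,
          mean = as.list(fit$mean),
          covariance = unname(apply(fit$covariance, 1, as.list)),
          epsilon = fit$epsilon, n_train = fit$n_train,
          regularization = fit$regularization)
      }
    }
    jsonlite::write_json(models, file.path(out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  cfg_json <- config
  cfg_json$cohort$route$grade_segments <-
    as.data.frame(cfg_json$cohort$route$grade_segments)
  jsonlite::write_json(
    rapply(unclass(cfg_json), unclass, how = "replace"),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, null = "null")
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
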