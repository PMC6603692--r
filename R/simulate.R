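#' Runner profile for the synthetic cohort generator
#'
#' A runner profile holds everything needed to simulate one runner's gait
#' records: the runner's mean 6-vector over the IMU variables (see
#' [gait_variables()]), the within-run covariance of the per-record noise, the
#' run-to-run SD of the additive run-level mean shift, condition-specific
#' additive effects (how the runner's gait shifts on uphill and downhill
#' grades), and the runner's typical running speed.
#'
#' @param runner_id Identifier (coerced to character).
#' @param mu Numeric 6-vector of per-variable means, in the units of
#'   [gait_variables()] (steps/min, cm, ms, m/s, deg, deg).
#' @param sigma 6x6 symmetric positive semi-definite within-run covariance.
#' @param between_run_sd Numeric 6-vector; SD of the run-level mean shift
#'   drawn once per run.
#' @param condition_effects Named list with numeric 6-vectors `level`,
#'   `uphill`, `downhill`; additive shifts applied to records generated on the
#'   matching grade. Grades outside all bins use the `level` effect.
#' @param base_speed Typical running speed in m/s.
#' @return An object of class `runner_profile`.
#' @export
runner_profile <- function(runner_id, mu, sigma, between_run_sd,
                           condition_effects = NULL, base_speed = 2.4) {
  vars <- gait_variables()
  stopifnot(length(mu) == 6, length(between_run_sd) == 6,
            all(dim(sigma) == c(6, 6)))
  if (mu[1] <= 0) abort(paste0("runner ", runner_id, ": cadence mean must be > 0"))
  if (mu[3] <= 0) abort(paste0("runner ", runner_id, ": ground contact time mean must be > 0"))
  if (!is_psd(sigma)) {
    abort(paste0("runner ", runner_id,
                 ": within-run covariance is not symmetric positive semi-definite"))
  }
  if (any(between_run_sd < 0)) abort("between_run_sd must be non-negative")
  zero <- stats::setNames(rep(0, 6), vars)
  condition_effects <- condition_effects %||% list()
  eff <- list(
    level = condition_effects$level %||% zero,
    uphill = condition_effects$uphill %||% zero,
    downhill = condition_effects$downhill %||% zero
  )
  eff <- lapply(eff, function(e) stats::setNames(as.numeric(e), vars))
  structure(
    list(runner_id = as.character(runner_id),
         mu = stats::setNames(as.numeric(mu), vars),
         sigma = `dimnames<-`(as.matrix(sigma), list(vars, vars)),
         between_run_sd = stats::setNames(as.numeric(between_run_sd), vars),
         condition_effects = eff,
         base_speed = as.numeric(base_speed)),
    class = "runner_profile"
  )
}

#' Route specification for simulated runs
#'
#' Describes the course a simulated run follows: an ordered sequence of grade
#' segments, per-second speed noise, and a per-kilometre probability of a
#' brief sub-1.8 m/s pause (traffic lights, water stops) that the speed gate
#' downstream should remove.
#'
#' @param grade_segments Data frame with columns `length_m` (>= 100) and
#'   `grade_pct`. Defaults to a 12 km mixed-elevation course.
#' @param speed_noise_sd Per-second speed noise SD, m/s.
#' @param stop_probability Per-kilometre probability of a pause.
#' @return An object of class `route_spec`.
#' @export
route_spec <- function(grade_segments = default_route_segments(),
                       speed_noise_sd = 0.15, stop_probability = 0.05) {
  grade_segments <- tibble::as_tibble(grade_segments)
  stopifnot(all(c("length_m", "grade_pct") %in% names(grade_segments)))
  if (any(grade_segments$length_m < 100)) {
    abort("route grade segments must each be at least 100 m long")
  }
  total_km <- sum(grade_segments$length_m) / 1000
  structure(
    list(total_km = total_km, grade_segments = grade_segments,
         speed_noise_sd = speed_noise_sd, stop_probability = stop_probability),
    class = "route_spec"
  )
}

#' Default mixed-elevation course
#'
#' A deterministic 12 km course built from repeated 2 km blocks of level,
#' uphill and downhill stretches (roughly 35% level, 30% uphill, 30% downhill,
#' 5% in the unclassified 2-3% band), with slight block-to-block grade
#' variation. Runs of at least 12 km match the study design of seven runs of
#' >= 12 km each.
#'
#' @param total_km Course length, km (multiples of 2 km blocks; >= 12 by
#'   default).
#' @return Tibble with `length_m` and `grade_pct`.
#' @export
default_route_segments <- function(total_km = 12) {
  block <- tibble::tibble(
    length_m = c(700, 600, 100, 600),
    grade_pct = c(0.8, 5.0, 2.5, -5.0)
  )
  n_block <- max(1L, ceiling(total_km * 1000 / sum(block$length_m)))
  jig <- c(0, 0.6, -0.4, 0.9, -0.7, 0.3) # deterministic block-to-block variety
  out <- purrr::map_dfr(seq_len(n_block), function(b) {
    j <- jig[((b - 1L) %% length(jig)) + 1L]
    dplyr::mutate(block, grade_pct = .data$grade_pct +
                    j * sign(.data$grade_pct + 0.1))
  })
  out
}

#' Random runner-specific course
#'
#' Draws a course with runner-specific terrain composition, emulating a
#' cohort whose running routes are not controlled: total length uniform on
#' `total_km_range`; shares of level / uphill / downhill / gap-grade (2-3%)
#' terrain drawn from a Dirichlet distribution around
#' `shares_mean` with concentration `shares_conc`; segment lengths uniform
#' on 300-800 m; segment grades uniform within the respective condition bin.
#' The resulting spread of per-condition distances across runners is wide,
#' matching observational cohorts where per-condition totals vary by
#' ~50% of their mean.
#'
#' @param seed Integer seed.
#' @param total_km_range Course length range, km.
#' @param shares_mean Mean terrain shares (level, uphill, downhill, gap).
#' @param shares_conc Dirichlet concentration; smaller = more heterogeneous.
#' @param speed_noise_sd,stop_probability Passed to [route_spec()].
#' @return A [route_spec()].
#' @export
random_route <- function(seed, total_km_range = c(12, 16),
                         shares_mean = c(0.37, 0.28, 0.28, 0.07),
                         shares_conc = 6, speed_noise_sd = 0.15,
                         stop_probability = 0.05) {
  with_seed(seed, {
    total_m <- runif(1, total_km_range[1], total_km_range[2]) * 1000
    g <- stats::rgamma(4, shape = shares_mean * shares_conc)
    shares <- g / sum(g)
    grade_rng <- list(level = c(-1.8, 1.8), uphill = c(3.2, 7.5),
                      downhill = c(-7.5, -3.2), gap = c(2.1, 2.9))
    segs <- list()
    for (k in seq_len(4)) {
      remaining <- shares[k] * total_m
      while (remaining >= 100) {
        len <- min(remaining, runif(1, 300, 800))
        if (remaining - len < 100) len <- remaining # absorb small tails
        gr <- runif(1, grade_rng[[k]][1], grade_rng[[k]][2])
        if (k == 4 && runif(1) < 0.5) gr <- -gr # gap grades go both ways
        segs[[length(segs) + 1L]] <- c(len, gr)
        remaining <- remaining - len
      }
    }
    segs <- segs[sample(length(segs))]
    route_spec(
      grade_segments = tibble::tibble(
        length_m = vapply(segs, `[`, numeric(1), 1),
        grade_pct = vapply(segs, `[`, numeric(1), 2)),
      speed_noise_sd = speed_noise_sd, stop_probability = stop_probability
    )
  })
}

#' Population-level cohort configuration
#'
#' Hyperparameters from which runner profiles are drawn: population means and
#' runner-to-runner SDs for the six IMU variables, the shared within-run
#' correlation structure and SD scale, run-to-run shift SDs, population
#' condition effects (with runner-specific deviations), and speed. Values are
#' package defaults chosen to be physiologic for recreational distance
#' runners at about 2.4 m/s; they are not estimates from any particular
#' dataset.
#'
#' @param mu_pop Population means for the six variables.
#' @param mu_sd_pop Runner-to-runner SD of the means.
#' @param within_sd Within-run record-to-record SDs.
#' @param within_cor 6x6 within-run correlation matrix.
#' @param between_run_sd Run-to-run mean-shift SDs (common scale; each
#'   runner's vector is jittered by a lognormal factor).
#' @param uphill_effect,downhill_effect Population additive effects applied on
#'   uphill / downhill grades. The default downhill effect includes a larger
#'   braking magnitude, reflecting the greater braking demands of downhill
#'   running.
#' @param effect_sd Runner-specific SD around the population condition
#'   effects.
#' @param base_speed_mean,base_speed_sd Typical speed distribution, m/s.
#' @param route A [route_spec()] shared by every runner, or `NULL` (default)
#'   to draw a runner-specific [random_route()] — the study's uncontrolled
#'   real-world routes.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(mu_pop = c(164, 8.5, 255, 0.28, 8.0, 10.0),
                          mu_sd_pop = c(8, 1.2, 18, 0.06, 2.0, 2.5),
                          within_sd = c(3, 0.6, 12, 0.05, 1.2, 1.8),
                          within_cor = default_within_cor(),
                          between_run_sd = c(1.5, 0.3, 6, 0.02, 0.6, 0.9),
                          uphill_effect = c(3, -0.8, 8, -0.04, 0.4, 1.0),
                          downhill_effect = c(-2, 0.6, -6, 0.08, 0.5, 0.8),
                          effect_sd = c(1.5, 0.4, 5, 0.03, 0.5, 0.8),
                          base_speed_mean = 2.4, base_speed_sd = 0.15,
                          route = NULL) {
  cfg <- list(mu_pop = mu_pop, mu_sd_pop = mu_sd_pop, within_sd = within_sd,
              within_cor = within_cor, between_run_sd = between_run_sd,
              uphill_effect = uphill_effect, downhill_effect = downhill_effect,
              effect_sd = effect_sd, base_speed_mean = base_speed_mean,
              base_speed_sd = base_speed_sd, route = route)
  lens <- lengths(cfg[c("mu_pop", "mu_sd_pop", "within_sd", "between_run_sd",
                        "uphill_effect", "downhill_effect", "effect_sd")])
  if (any(lens != 6)) abort("all per-variable hyperparameters must have length 6")
  if (!is_psd(within_cor)) abort("within_cor must be positive semi-definite")
  if (!is.null(route) && !inherits(route, "route_spec")) {
    abort("route must be NULL or a route_spec()")
  }
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_within_cor <- function() {
  v <- gait_variables()
  C <- diag(6)
  dimnames(C) <- list(v, v)
  set_cor <- function(C, a, b, r) { C[a, b] <- r; C[b, a] <- r; C }
  C <- set_cor(C, "cadence_spm", "vosc_cm", -0.3)
  C <- set_cor(C, "cadence_spm", "gct_ms", -0.5)
  C <- set_cor(C, "vosc_cm", "gct_ms", 0.3)
  C <- set_cor(C, "vosc_cm", "braking_ms", 0.2)
  C <- set_cor(C, "gct_ms", "braking_ms", 0.2)
  C <- set_cor(C, "pdrop_deg", "prot_deg", 0.3)
  C
}

## draw one runner profile from the population config
draw_profile <- function(runner_id, config, seed) {
  with_seed(seed, {
    mu <- rnorm(6, config$mu_pop, config$mu_sd_pop)
    mu[1] <- max(mu[1], 120) # cadence stays physiologic
    mu[3] <- max(mu[3], 180)
    sd_i <- config$within_sd * exp(rnorm(6, 0, 0.10))
    sigma <- diag(sd_i) %*% config$within_cor %*% diag(sd_i)
    sigma <- (sigma + t(sigma)) / 2
    brs <- config$between_run_sd * exp(rnorm(1, 0, 0.2))
    eff <- list(
      level = rep(0, 6),
      uphill = rnorm(6, config$uphill_effect, config$effect_sd),
      downhill = rnorm(6, config$downhill_effect, config$effect_sd)
    )
    runner_profile(runner_id, mu, sigma, brs, eff,
                   base_speed = max(1.9, rnorm(1, config$base_speed_mean,
                                               config$base_speed_sd)))
  })
}

## piecewise-linear altitude profile and grade lookup for a route
route_profile <- function(route) {
  seg <- route$grade_segments
  ends <- cumsum(seg$length_m)
  starts <- c(0, head(ends, -1))
  alt_ends <- cumsum(seg$length_m * seg$grade_pct / 100)
  alt_starts <- c(0, head(alt_ends, -1))
  list(
    total_m = sum(seg$length_m),
    grade_at = function(d) {
      i <- findInterval(pmin(pmax(d, 0), sum(seg$length_m) - 1e-9), starts)
      seg$grade_pct[i]
    },
    alt_at = function(d) {
      d <- pmin(pmax(d, 0), sum(seg$length_m))
      i <- findInterval(d, starts, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1L), nrow(seg))
      alt_starts[i] + (d - starts[i]) * seg$grade_pct[i] / 100
    }
  )
}

#' Simulate one run (GPS and IMU stream) for a runner
#'
#' Generates a 1 Hz GPS stream (speed, altitude, cumulative distance,
#' latitude/longitude along a straight bearing) over the route, and an IMU
#' stream with one record per five strides. The record interval is recomputed
#' from each record's own cadence draw: with a stride of two steps, five
#' strides are ten steps, so `dt = 600 / cadence_spm` seconds. A run-level
#' mean shift is drawn once from `between_run_sd`; each record adds the
#' condition effect of the true route grade under its position, providing
#' ground-truth condition labels for segmentation tests.
#'
#' @param profile A [runner_profile()].
#' @param route A [route_spec()].
#' @param seed Integer seed (required; runs are reproducible).
#' @param run_id Run identifier stored in the output.
#' @return List with tibbles `gps` (`runner_id, run_id, t_s, speed_ms,
#'   altitude_m, dist_km, lat, lon`) and `imu` (`runner_id, run_id, t_s`, the
#'   six gait variables, plus ground-truth `grade_true` and `condition_true`).
#' @export
simulate_run <- function(profile, route, seed, run_id = 1L) {
  stopifnot(inherits(profile, "runner_profile"), inherits(route, "route_spec"))
  if (profile$mu["cadence_spm"] <= 0) abort("cadence mean must be positive")
  rp <- route_profile(route)
  with_seed(seed, {
    total_m <- rp$total_m
    ## per-second speeds, with optional pauses spliced in at km marks
    n_guess <- ceiling(total_m / max(0.5, profile$base_speed - 1)) + 60L
    spd <- pmax(0.5, rnorm(n_guess, profile$base_speed, route$speed_noise_sd))
    n_km <- floor(total_m / 1000)
    stop_km <- which(runif(n_km) < route$stop_probability)
    for (km in stop_km) {
      cd <- cumsum(spd)
      at <- which(cd >= km * 1000)[1]
      if (is.na(at)) next
      pause <- pmax(0.3, rnorm(round(runif(1, 20, 40)), 1.0, 0.25))
      spd <- append(spd, pause, after = at)
    }
    cd <- cumsum(spd)
    n_keep <- which(cd >= total_m)[1]
    if (is.na(n_keep)) n_keep <- length(spd)
    spd <- spd[seq_len(n_keep)]
    dist_m <- cumsum(spd)
    t_s <- seq_len(n_keep)
    alt <- rp$alt_at(dist_m)
    gps <- tibble::tibble(
      runner_id = profile$runner_id, run_id = as.integer(run_id),
      t_s = as.numeric(t_s), speed_ms = spd, altitude_m = alt,
      dist_km = dist_m / 1000,
      lat = 51.05 + dist_m / 111320, lon = -114.07
    )

    ## IMU records every five strides, co-registered by the shared clock
    run_shift <- rnorm(6, 0, profile$between_run_sd)
    R <- if (all(profile$sigma == 0)) NULL else chol_psd(profile$sigma)
    dist_at <- stats::approxfun(t_s, dist_m, rule = 2)
    n_max <- ceiling(n_keep / 2) + 8L
    Z <- matrix(rnorm(n_max * 6), ncol = 6)
    rec_t <- numeric(n_max); X <- matrix(NA_real_, n_max, 6)
    grade_true <- numeric(n_max)
    t_cur <- 1.0; i <- 0L
    while (t_cur <= n_keep && i < n_max) {
      i <- i + 1L
      g <- rp$grade_at(dist_at(t_cur))
      cond <- classify_grade(g)
      eff <- profile$condition_effects[[if (cond == "unclassified") "level" else cond]]
      x <- profile$mu + run_shift + eff
      if (!is.null(R)) x <- x + drop(Z[i, ] %*% R)
      rec_t[i] <- t_cur; X[i, ] <- x; grade_true[i] <- g
      cad <- max(x[1], 40) # timing guard against extreme draws
      t_cur <- t_cur + 600 / cad
    }
    keep <- seq_len(i)
    imu <- tibble::tibble(
      runner_id = profile$runner_id, run_id = as.integer(run_id),
      t_s = rec_t[keep]
    )
    imu[gait_variables()] <- as.data.frame(X[keep, , drop = FALSE])
    imu$grade_true <- grade_true[keep]
    imu$condition_true <- classify_grade(grade_true[keep])
    list(gps = gps, imu = imu)
  })
}

#' Simulate a cohort of runners and runs
#'
#' Draws `n_runners` profiles from the population configuration and simulates
#' `n_runs` runs for each, mirroring the study design of 35 recreational
#' runners performing seven runs of at least 12 km. All randomness descends
#' deterministically from `seed`: the same call returns bit-identical output.
#'
#' @param n_runners Number of runners (>= 1).
#' @param n_runs Runs per runner (>= 2).
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return An object of class `gait_cohort`: a list with tibbles `imu` and
#'   `gps` stacked over all runs, the list of `profiles`, plus `config` and
#'   `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(n_runners = 2, n_runs = 2, seed = 1)
#' dplyr::count(coh$imu, runner_id, run_id)
simulate_cohort <- function(n_runners = 35, n_runs = 7,
                            config = cohort_config(), seed) {
  stopifnot(n_runners >= 1, n_runs >= 2)
  if (missing(seed)) abort("simulate_cohort() requires an explicit seed")
  if (!inherits(config, "cohort_config")) abort("config must be a cohort_config()")
  profiles <- lapply(seq_len(n_runners), function(r) {
    draw_profile(sprintf("R%02d", r), config, derive_seed(seed, 1L, r))
  })
  routes <- lapply(seq_len(n_runners), function(r) {
    config$route %||% random_route(derive_seed(seed, 5L, r))
  })
  names(routes) <- purrr::map_chr(profiles, "runner_id")
  runs <- purrr::map(seq_len(n_runners), function(r) {
    purrr::map(seq_len(n_runs), function(k) {
      simulate_run(profiles[[r]], routes[[r]],
                   seed = derive_seed(seed, 2L, r, k), run_id = k)
    })
  })
  flat <- purrr::flatten(runs)
  structure(
    list(imu = dplyr::bind_rows(purrr::map(flat, "imu")),
         gps = dplyr::bind_rows(purrr::map(flat, "gps")),
         profiles = stats::setNames(profiles, purrr::map_chr(profiles, "runner_id")),
         routes = routes, config = config, seed = seed),
    class = "gait_cohort"
  )
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat("<gait_cohort> ", length(x$profiles), " runners x ",
      max(x$imu$run_id), " runs; ", nrow(x$imu), " IMU records, ",
      nrow(x$gps), " GPS samples (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to CSV files plus a ground-truth JSON
#'
#' One IMU CSV and one GPS CSV per run (named
#' `imu_<runner>_run<k>.csv` / `gps_<runner>_run<k>.csv`), and
#' `ground_truth.json` holding each profile's generating parameters and the
#' master seed, so segmentation and recovery tests can compare against truth.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  by_run <- function(df) split(df, interaction(df$runner_id, df$run_id, drop = TRUE))
  for (piece in by_run(cohort$imu)) {
    f <- sprintf("imu_%s_run%d.csv", piece$runner_id[1], piece$run_id[1])
    readr::write_csv(dplyr::select(piece, -dplyr::any_of(c("grade_true", "condition_true"))),
                     file.path(dir, f))
  }
  for (piece in by_run(cohort$gps)) {
    f <- sprintf("gps_%s_run%d.csv", piece$runner_id[1], piece$run_id[1])
    readr::write_csv(piece, file.path(dir, f))
  }
  truth <- list(
    seed = cohort$seed,
    profiles = lapply(cohort$profiles, function(p) {
      list(runner_id = p$runner_id, mu = as.list(p$mu),
           sigma = unname(apply(p$sigma, 1, as.list)),
           between_run_sd = as.list(p$between_run_sd),
           condition_effects = lapply(p$condition_effects, as.list),
           base_speed = p$base_speed)
    }),
    imu_truth = cohort$imu[, c("runner_id", "run_id", "t_s",
                               "grade_true", "condition_true")]
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort back from the CSV layout written by [write_cohort()]
#'
#' Accepts any directory of `imu_*.csv` / `gps_*.csv` files using the same
#' headers (including real exports).
#'
#' @param dir Directory containing the CSVs.
#' @return List with tibbles `imu` and `gps`.
#' @export
read_cohort_csv <- function(dir) {
  imu_files <- list.files(dir, "^imu_.*\\.csv$", full.names = TRUE)
  gps_files <- list.files(dir, "^gps_.*\\.csv$", full.names = TRUE)
  if (length(gps_files) == 0) abort(paste0("no GPS CSVs found under ", dir))
  list(
    imu = dplyr::bind_rows(lapply(imu_files, readr::read_csv,
                                  show_col_types = FALSE)),
    gps = dplyr::bind_rows(lapply(gps_files, readr::read_csv,
                                  show_col_types = FALSE))
  )
}
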