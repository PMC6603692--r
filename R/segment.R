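#' Centered moving-average smoother for 1 Hz series
#'
#' A 10 s centered moving average, truncated at the series edges (each output
#' value is the mean of the at-most-`window` samples available around it).
#' Applied to GPS speed and altitude before gating and windowing.
#'
#' @param x Numeric vector sampled at 1 Hz.
#' @param window Window length in seconds (samples).
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' smooth_series(c(rep(0, 5), 1, rep(0, 5)), window = 10)
smooth_series <- function(x, window = 10) {
  if (length(x) == 0) return(numeric(0))
  if (length(x) <= window) return(rep(mean(x), length(x)))
  zoo::rollapply(x, width = window, FUN = mean, partial = TRUE,
                 align = "center")
}

#' Classify a grade percentage into an elevation condition
#'
#' Bins follow the study definitions: level when |grade| <= 2%, uphill when
#' grade is in \[+3%, +15%\], downhill when in \[-15%, -3%\]. Grades in the
#' gaps (2-3% in magnitude, or beyond 15%) are `unclassified`: they belong to
#' no single-grade condition but still count toward the mixed condition.
#'
#' @param grade Numeric vector of grades, percent (rise/run x 100).
#' @return Character vector of condition labels.
#' @export
#' @examples
#' classify_grade(c(0, 3.24, -3.81, 2.5, 20))
classify_grade <- function(grade) {
  out <- rep("unclassified", length(grade))
  out[abs(grade) <= 2] <- "level"
  out[grade >= 3 & grade <= 15] <- "uphill"
  out[grade <= -3 & grade >= -15] <- "downhill"
  out[!is.finite(grade)] <- NA_character_
  out
}

#' Trim a run to the analysis distance range
#'
#' Discards the first `warmup_km` (warmup) and everything beyond `cap_km`
#' (fatigue guard), keeping samples with cumulative distance in
#' \[warmup_km, cap_km\]. IMU records are positioned by linear interpolation
#' of the GPS cumulative distance at the record timestamp (the streams share
#' a clock) and trimmed to the same range; no IMU record before the first GPS
#' sample is kept.
#'
#' @param gps Single-run GPS tibble (`t_s`, `speed_ms`, `altitude_m`,
#'   `dist_km`).
#' @param imu Single-run IMU tibble (`t_s` + gait variables), or `NULL`.
#' @param warmup_km,cap_km Trim bounds, km.
#' @return List of trimmed `gps` and `imu` tibbles (the latter with a
#'   `dist_km` column added).
#' @export
trim_run <- function(gps, imu = NULL, warmup_km = 1, cap_km = 10) {
  stopifnot(all(c("t_s", "dist_km") %in% names(gps)))
  if (nrow(gps) == 0 || max(gps$dist_km) < warmup_km) {
    warn(sprintf("run shorter than %g km; nothing retained", warmup_km))
    gps_out <- gps[0, ]
    imu_out <- if (is.null(imu)) NULL else dplyr::mutate(imu[0, ], dist_km = numeric(0))
    return(list(gps = gps_out, imu = imu_out))
  }
  gps_out <- dplyr::filter(gps, .data$dist_km >= warmup_km, .data$dist_km <= cap_km)
  imu_out <- NULL
  if (!is.null(imu)) {
    d_at <- stats::approxfun(gps$t_s, gps$dist_km, rule = 2)
    imu_out <- dplyr::mutate(imu, dist_km = d_at(.data$t_s))
    imu_out <- dplyr::filter(imu_out, .data$t_s >= min(gps$t_s),
                             .data$dist_km >= warmup_km, .data$dist_km <= cap_km)
  }
  list(gps = gps_out, imu = imu_out)
}

#' Keep only actively-running GPS samples
#'
#' Removes samples whose smoothed speed is below `min_speed` (1.8 m/s in the
#' study), so that pauses and walking do not enter the analysis. Expects a
#' `speed_smooth` column (added by the segmentation pipeline); falls back to
#' smoothing `speed_ms` if absent.
#'
#' @param gps GPS tibble.
#' @param min_speed Threshold, m/s.
#' @return The retained subset of rows.
#' @export
filter_active <- function(gps, min_speed = 1.8) {
  if (!"speed_smooth" %in% names(gps)) {
    gps <- dplyr::mutate(gps, speed_smooth = smooth_series(.data$speed_ms))
  }
  dplyr::filter(gps, .data$speed_smooth >= min_speed)
}

## per-run segmentation core; gps/imu are single-run tibbles
segment_one_run <- function(gps, imu, min_speed = 1.8, window_m = 100,
                            warmup_km = 1, cap_km = 10, smooth_s = 10) {
  empty <- list(
    gps = tibble::tibble(), windows = tibble::tibble(), records = tibble::tibble()
  )
  tr <- withCallingHandlers(
    trim_run(gps, imu, warmup_km = warmup_km, cap_km = cap_km),
    warning = function(w) invokeRestart("muffleWarning")
  )
  g <- tr$gps
  if (nrow(g) < 2) return(empty)
  g <- dplyr::mutate(
    g,
    speed_smooth = smooth_series(.data$speed_ms, smooth_s),
    alt_smooth = smooth_series(.data$altitude_m, smooth_s),
    dist_m = .data$dist_km * 1000
  )
  ## retained running distance: increments of low-speed seconds contribute 0
  inc <- c(0, diff(g$dist_m))
  active <- g$speed_smooth >= min_speed
  rdist <- cumsum(ifelse(active, inc, 0))
  ga <- dplyr::mutate(g[active, , drop = FALSE], rdist_m = rdist[active])
  if (nrow(ga) < 2 || max(ga$rdist_m) < window_m) return(empty)

  n_win <- floor(max(ga$rdist_m) / window_m)
  bounds <- seq(0, n_win * window_m, by = window_m)
  alt_b <- stats::approx(ga$rdist_m, ga$alt_smooth, xout = bounds,
                         ties = "ordered", rule = 2)$y
  windows <- tibble::tibble(
    runner_id = ga$runner_id[1], run_id = ga$run_id[1],
    window = seq_len(n_win),
    start_m = bounds[-length(bounds)], end_m = bounds[-1],
    grade_pct = diff(alt_b) / window_m * 100
  )
  windows$condition <- classify_grade(windows$grade_pct)

  ga$window <- pmin(findInterval(ga$rdist_m, bounds,
                                 left.open = FALSE), n_win + 1L)
  ga$window[ga$window > n_win] <- NA_integer_
  ga$condition <- ifelse(is.na(ga$window), "unclassified",
                         windows$condition[ga$window])

  rec <- tr$imu
  if (!is.null(rec) && nrow(rec) > 0) {
    sp_at <- stats::approxfun(g$t_s, g$speed_smooth, rule = 2)
    rec <- dplyr::filter(rec, sp_at(.data$t_s) >= min_speed,
                         .data$t_s >= min(ga$t_s), .data$t_s <= max(ga$t_s))
  }
  if (!is.null(rec) && nrow(rec) > 0) {
    rd_at <- stats::approxfun(ga$t_s, ga$rdist_m, rule = 2, ties = "ordered")
    rec$rdist_m <- rd_at(rec$t_s)
    w <- findInterval(rec$rdist_m, bounds, left.open = FALSE)
    w[w > n_win | w < 1] <- NA_integer_
    rec$window <- w
    rec$grade_pct <- ifelse(is.na(w), NA_real_, windows$grade_pct[w])
    rec$condition <- ifelse(is.na(w), "unclassified", windows$condition[w])
  } else {
    rec <- tibble::tibble()
  }
  list(gps = ga, windows = windows, records = rec)
}

#' Segment a cohort's runs into elevation-condition datasets
#'
#' The full segmentation pipeline, applied per run: trim to the analysis
#' range (first km discarded, capped at 10 km), smooth speed and altitude
#' with a 10 s moving average, drop samples below the running-speed gate,
#' accumulate retained running distance, cut it into consecutive
#' non-overlapping 100 m windows, grade each window from the smoothed
#' altitude at its boundaries, classify windows into conditions, and assign
#' every retained IMU record the condition of the window containing it.
#' Records beyond the last full window carry `unclassified` and count only
#' toward the mixed condition. Windows are exactly `window_m` of retained
#' running, so every contiguous same-condition section is at least 100 m
#' long by construction.
#'
#' @param x A [simulate_cohort()] result, or a GPS tibble covering one or
#'   more runs (`runner_id`, `run_id`, `t_s`, `speed_ms`, `altitude_m`,
#'   `dist_km`).
#' @param imu Matching IMU tibble (ignored when `x` is a cohort).
#' @param min_speed Running-speed gate, m/s.
#' @param window_m Elevation window length, m.
#' @param warmup_km,cap_km Trim bounds, km.
#' @param smooth_s Moving-average window, s.
#' @return An object of class `gait_segmentation`: list of tibbles `records`
#'   (one row per retained IMU record, with `window`, `grade_pct`,
#'   `condition` and the six gait variables), `windows` (per 100 m window)
#'   and `gps` (retained samples with `rdist_m`, `window`, `condition`).
#' @export
#' @examples
#' coh <- simulate_cohort(n_runners = 1, n_runs = 2, seed = 3)
#' seg <- segment_runs(coh)
#' dplyr::count(seg$records, condition)
segment_runs <- function(x, imu = NULL, min_speed = 1.8, window_m = 100,
                         warmup_km = 1, cap_km = 10, smooth_s = 10) {
  if (inherits(x, "gait_cohort")) {
    gps <- x$gps
    imu <- x$imu
  } else {
    gps <- x
  }
  stopifnot(all(c("runner_id", "run_id") %in% names(gps)))
  key <- interaction(gps$runner_id, gps$run_id, drop = TRUE)
  gps_split <- split(gps, key)
  imu_split <- if (!is.null(imu)) {
    split(imu, factor(interaction(imu$runner_id, imu$run_id, drop = TRUE),
                      levels = levels(key)))
  }
  parts <- purrr::imap(gps_split, function(g, k) {
    segment_one_run(g, imu_split[[k]], min_speed = min_speed,
                    window_m = window_m, warmup_km = warmup_km,
                    cap_km = cap_km, smooth_s = smooth_s)
  })
  out <- structure(
    list(records = dplyr::bind_rows(purrr::map(parts, "records")),
         windows = dplyr::bind_rows(purrr::map(parts, "windows")),
         gps = dplyr::bind_rows(purrr::map(parts, "gps")),
         params = list(min_speed = min_speed, window_m = window_m,
                       warmup_km = warmup_km, cap_km = cap_km,
                       smooth_s = smooth_s)),
    class = "gait_segmentation"
  )
  out
}

#' @export
print.gait_segmentation <- function(x, ...) {
  cat("<gait_segmentation> ", nrow(x$records), " IMU records in ",
      nrow(x$windows), " windows (", x$params$window_m, " m)\n", sep = "")
  if (nrow(x$records) > 0) {
    tab <- table(x$records$condition)
    cat("  records by condition: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract one condition's records from segmented data
#'
#' `mixed` returns every retained record (the entire run irrespective of
#' elevation); any other condition returns the records whose window carries
#' that label. Each record therefore appears in mixed exactly once and in at
#' most one single-grade condition.
#'
#' @param x A `gait_segmentation` or its `records` tibble.
#' @param condition One of [gait_conditions()].
#' @return Tibble of records.
#' @export
condition_records <- function(x, condition) {
  records <- if (inherits(x, "gait_segmentation")) x$records else x
  condition <- match.arg(condition, gait_conditions(include_unclassified = TRUE))
  if (condition == "mixed") return(records)
  dplyr::filter(records, .data$condition == !!condition)
}

#' Per-condition cohort summary (distance, inclination, speed)
#'
#' For each condition: per-run totals of retained distance (km), mean window
#' inclination (%) and mean sample speed (m/s), averaged (mean, SD) over all
#' runs in the cohort — the shape of a study characteristics table.
#'
#' @param seg A `gait_segmentation`.
#' @return Tibble with one row per condition.
#' @export
summarize_conditions <- function(seg) {
  stopifnot(inherits(seg, "gait_segmentation"))
  if (nrow(seg$windows) == 0) {
    return(tibble::tibble(condition = character(), dist_km_mean = numeric(),
                          dist_km_sd = numeric(), incl_mean = numeric(),
                          incl_sd = numeric(), speed_mean = numeric(),
                          speed_sd = numeric()))
  }
  wkm <- seg$params$window_m / 1000
  per_run <- function(cond) {
    w <- if (cond == "mixed") seg$windows else
      dplyr::filter(seg$windows, .data$condition == cond)
    g <- if (cond == "mixed") dplyr::filter(seg$gps, !is.na(.data$window)) else
      dplyr::filter(seg$gps, .data$condition == cond)
    if (nrow(w) == 0) return(NULL)
    wsum <- dplyr::summarise(
      dplyr::group_by(w, .data$runner_id, .data$run_id),
      dist_km = dplyr::n() * wkm, incl = mean(.data$grade_pct), .groups = "drop")
    gsum <- dplyr::summarise(
      dplyr::group_by(g, .data$runner_id, .data$run_id),
      speed = mean(.data$speed_ms), .groups = "drop")
    dplyr::mutate(dplyr::left_join(wsum, gsum, by = c("runner_id", "run_id")),
                  condition = cond)
  }
  runs <- dplyr::bind_rows(lapply(gait_conditions(), per_run))
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  out <- dplyr::summarise(
    dplyr::group_by(runs, .data$condition),
    dist_km_mean = mean(.data$dist_km), dist_km_sd = sd0(.data$dist_km),
    incl_mean = mean(.data$incl), incl_sd = sd0(.data$incl),
    speed_mean = mean(.data$speed, na.rm = TRUE),
    speed_sd = sd0(.data$speed[!is.na(.data$speed)]),
    .groups = "drop")
  out[match(gait_conditions(), out$condition), , drop = FALSE] |>
    dplyr::filter(!is.na(.data$condition))
}
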