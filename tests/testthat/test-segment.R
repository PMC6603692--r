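test_that("moving-average smoother matches direct convolution", {
  expect_equal(smooth_series(rep(3.3, 50)), rep(3.3, 50))

  imp <- c(rep(0, 14), 1, rep(0, 15))
  sm <- smooth_series(imp, window = 10)
  expect_equal(sum(sm), 1)                      # mass preserved
  expect_setequal(round(unique(sm), 10), c(0, 0.1)) # affected samples = 1/10

  short <- c(1, 2, 3, 4)
  expect_equal(smooth_series(short, window = 10), rep(mean(short), 4))
  expect_identical(smooth_series(numeric(0)), numeric(0))
})

test_that("grade bins classify per the stated condition definitions", {
  expect_equal(classify_grade(0), "level")
  expect_equal(classify_grade(3.24), "uphill")     # an observed uphill mean grade
  expect_equal(classify_grade(-3.81), "downhill")  # an observed downhill mean grade
  expect_equal(classify_grade(2.5), "unclassified") # the (2,3)% gap
  expect_equal(classify_grade(c(-2, 2)), c("level", "level"))   # closed at +/-2
  expect_equal(classify_grade(c(3, 15, -3, -15)),
               c("uphill", "uphill", "downhill", "downhill"))   # closed endpoints
  expect_equal(classify_grade(c(2.0001, 16, -20)), rep("unclassified", 3))
  expect_true(is.na(classify_grade(NaN)))
})

test_that("runs are trimmed to the warmup/cap distance range", {
  gps <- synthetic_gps(total_m = 12000, speed = 2.0)
  imu <- tibble::tibble(t_s = seq(5, 5900, by = 4), cadence_spm = 160)
  tr <- trim_run(gps, imu)
  expect_equal(range(tr$gps$dist_km), c(1, 10), tolerance = 1e-3)
  expect_true(all(tr$imu$dist_km >= 1 & tr$imu$dist_km <= 10))

  short <- trim_run(synthetic_gps(total_m = 5000, speed = 2.0))
  expect_equal(range(short$gps$dist_km), c(1, 5), tolerance = 1e-3)

  expect_warning(res <- trim_run(synthetic_gps(total_m = 800)), "shorter")
  expect_equal(nrow(res$gps), 0)
})

test_that("speed gate keeps only actively-running samples", {
  gps <- tibble::tibble(t_s = 1:3, speed_ms = c(1.0, 2.0, 1.7),
                        speed_smooth = c(1.0, 2.0, 1.7))
  expect_equal(filter_active(gps)$speed_smooth, 2.0)
  expect_equal(nrow(filter_active(dplyr::mutate(gps, speed_smooth = 1.5))), 0)
  all_fast <- dplyr::mutate(gps, speed_smooth = 2.0)
  expect_equal(nrow(filter_active(all_fast)), 3)
})

test_that("elevation windows are 100 m with grades from smoothed altitude", {
  seg <- segment_runs(synthetic_gps(total_m = 12000, speed = 2.5, grade = 5))
  w <- seg$windows
  expect_true(all(w$end_m - w$start_m == 100))
  expect_equal(nrow(w), 90)                      # 9 km retained
  expect_equal(median(w$grade_pct), 5, tolerance = 1e-6)
  expect_true(all(abs(w$grade_pct - 5) < 0.35))  # edge-smoothing wiggle only
  expect_true(all(w$condition == "uphill"))

  flat <- segment_runs(synthetic_gps(total_m = 12000, speed = 2.5, grade = 0))
  expect_true(all(flat$windows$grade_pct == 0))
  expect_true(all(flat$windows$condition == "level"))

  ## 950 m of retained data -> 9 windows, trailing 50 m dropped
  part <- segment_runs(synthetic_gps(total_m = 1950, speed = 2.5))
  expect_equal(nrow(part$windows), 9)
})

test_that("records map to half-open windows by retained distance", {
  gps <- synthetic_gps(total_m = 12000, speed = 2.5)
  ## retained distance starts at the 1 km trim point; 1050 m in -> dist 2050 m
  imu <- tibble::tibble(runner_id = "S1", run_id = 1L, t_s = 2050 / 2.5,
                        cadence_spm = 160, vosc_cm = 8, gct_ms = 250,
                        braking_ms = 0.3, pdrop_deg = 8, prot_deg = 10)
  seg <- segment_runs(gps, imu)
  expect_equal(seg$records$window, 11L)   # [1000, 1100) is the 11th window
  expect_equal(seg$records$rdist_m, 1050, tolerance = 2.5)
})

test_that("segmented conditions match generator ground truth away from boundaries", {
  coh <- fixture("coh_2x7", simulate_cohort(2, 7, seed = 1))
  seg <- fixture("seg_2x7", segment_runs(coh))
  rec <- seg$records

  ## partition: mixed holds every record once; graded bins partition the rest
  expect_equal(nrow(condition_records(seg, "mixed")), nrow(rec))
  n_by_bin <- vapply(c("level", "uphill", "downhill", "unclassified"),
                     function(cc) nrow(condition_records(seg, cc)), integer(1))
  expect_equal(sum(n_by_bin), nrow(rec))

  ## truth labels ride along from the generator
  j <- rec
  expect_true(all(c("condition", "condition_true") %in% names(j)))
  expect_gt(mean(j$condition == j$condition_true), 0.85)

  ## windows whose records share one true label (not straddling a terrain
  ## change), away from run edges, classify to that label
  per_win <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(j, !is.na(window)), runner_id, run_id, window),
    uniform = dplyr::n_distinct(condition_true) == 1,
    truth = condition_true[1], got = condition[1], .groups = "drop_last")
  per_win <- dplyr::ungroup(dplyr::mutate(per_win, n_win = max(window)))
  interior <- dplyr::filter(per_win, uniform, window > 1, window < n_win)
  expect_gt(mean(interior$got == interior$truth), 0.95)
})

test_that("trim and speed gate are idempotent", {
  gps <- synthetic_gps(total_m = 12000, speed = 2.5)
  t1 <- trim_run(gps)$gps
  expect_identical(trim_run(t1)$gps, t1)
  f1 <- filter_active(dplyr::mutate(t1, speed_smooth = speed_ms))
  expect_identical(filter_active(f1), f1)
})

test_that("condition summaries have the per-condition characteristics shape", {
  seg <- segment_runs(synthetic_gps(total_m = 12000, speed = 2.4))
  s <- summarize_conditions(seg)
  lv <- dplyr::filter(s, condition == "level")
  expect_equal(lv$speed_mean, 2.4, tolerance = 1e-6)
  expect_equal(lv$speed_sd, 0)
  expect_equal(lv$incl_mean, 0)
  expect_equal(lv$dist_km_mean, 9, tolerance = 0.11)

  empty <- structure(list(records = tibble::tibble(), windows = tibble::tibble(),
                          gps = tibble::tibble(), params = list(window_m = 100)),
                     class = "gait_segmentation")
  expect_equal(nrow(summarize_conditions(empty)), 0)
})
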