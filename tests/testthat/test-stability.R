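test_that("split enumeration matches binomial counts and brute force", {
  s <- enumerate_splits(1:7, 3)
  expect_equal(nrow(s), 35)
  expect_equal(sum(lengths(s$test)), 35 * 4) # one pair per left-out run

  full <- enumerate_splits(1:7, 7)
  expect_equal(nrow(full), 1)
  expect_equal(sum(lengths(full$test)), 0)

  s42 <- enumerate_splits(1:4, 2)
  expect_equal(nrow(s42), 6)
  expect_equal(sum(lengths(s42$test)), 12)
  brute <- combn(1:4, 2, simplify = FALSE)
  expect_identical(s42$train, brute)
  for (i in seq_len(6)) {
    expect_setequal(c(s42$train[[i]], s42$test[[i]]), 1:4)
    expect_length(intersect(s42$train[[i]], s42$test[[i]]), 0)
  }

  for (R in 2:10) {
    counts <- split_counts(R, pooled_complement = FALSE)
    expect_equal(counts$n_sets, choose(R, seq_len(R)))
    expect_equal(counts$n_pairs, choose(R, seq_len(R)) * (R - seq_len(R)))
    pub <- split_counts(R) # published accounting adds the pooled complement
    expect_equal(pub$n_pairs - counts$n_pairs,
                 choose(R, seq_len(R)) * (seq_len(R) < R))
    expect_equal(nrow(enumerate_splits(seq_len(R), 2)), choose(R, 2))
  }
  expect_error(enumerate_splits(1:4, 5), "between")
})

test_that("quantile change is |next-prev|/|prev| with a near-zero guard", {
  same <- quantile_change(c(1, 2), c(1, 2))
  expect_equal(c(same$delta_low, same$delta_high), c(0, 0))
  expect_equal(quantile_change(c(50, 100), c(50, 104))$delta_high, 4)
  expect_equal(quantile_change(c(-2, 1), c(-2.2, 1))$delta_low, 10)

  g <- quantile_change(c(0, 10), c(0.5, 10), abs_scale = 5)
  expect_true(g$absolute_low)
  expect_false(g$absolute_high)
  expect_equal(g$delta_low, 10) # 100 * 0.5 / 5
  expect_warning(quantile_change(c(0, 10), c(0.5, 10)), "abs_scale")
})

test_that("stability point follows the <5% quantile-change rule", {
  withr::with_seed(42, {
    base <- rnorm(300, 100, 1)
    ## three disruptive additions, then additions matching the pooled fit
    runs <- list(base, base + 10, base - 10, base + 25,
                 rnorm(300, 106.25, 12.6), rnorm(300, 106.25, 12.6),
                 rnorm(300, 106.25, 12.6))
    mats <- lapply(runs, function(r) matrix(r, ncol = 1, dimnames = list(NULL, "x")))
    sp <- stability_point(mats, "x")
    expect_equal(oracle_stability(runs), 4L)
    expect_equal(sp$stability_point, 4L)
    expect_true(sp$reached)
    expect_equal(nrow(sp$trace), 7)

    ## alternating large shifts never settle
    alt <- lapply(1:7, function(i) {
      matrix(base + ifelse(i %% 2 == 0, 60, 0), ncol = 1,
             dimnames = list(NULL, "x"))
    })
    sp_alt <- stability_point(alt, "x")
    expect_false(sp_alt$reached)
    expect_true(is.na(sp_alt$stability_point))
  })
})

test_that("stability point agrees with the definition-level oracle", {
  withr::with_seed(77, {
    for (rep in 1:8) {
      R <- sample(3:6, 1)
      runs <- lapply(seq_len(R), function(i) rnorm(60, sample(c(0, 4, 8), 1), 1 + runif(1)))
      mats <- lapply(runs, function(r) matrix(r, ncol = 1, dimnames = list(NULL, "x")))
      expect_equal(stability_point(mats, "x")$stability_point,
                   oracle_stability(runs))
    }
  })
})

test_that("zero between-run variance gives stability at one run", {
  prof <- test_profile(between = rep(0, 6))
  runs <- lapply(1:7, function(k) {
    simulate_run(prof, flat_route(), seed = 300 + k, run_id = k)$imu
  })
  for (vars in list("cadence_spm", gait_variables())) {
    sp <- stability_point(runs, vars)
    expect_equal(sp$stability_point, 1L)
  }
})

test_that("stability is invariant to affine rescaling of a univariate variable", {
  withr::with_seed(6, {
    runs <- lapply(1:5, function(i) {
      tibble::tibble(braking_ms = rnorm(80, 0.3 + 0.05 * (i %% 2), 0.05))
    })
    sp1 <- stability_point(runs, "braking_ms")
    sp2 <- stability_point(lapply(runs, function(r) r * 1000), "braking_ms")
    expect_equal(sp1$stability_point, sp2$stability_point)
  })
})

test_that("empty runs are skipped with re-indexing", {
  withr::with_seed(1, {
    runs <- list(matrix(rnorm(50), 50, 1, dimnames = list(NULL, "x")),
                 matrix(numeric(0), 0, 1, dimnames = list(NULL, "x")),
                 matrix(rnorm(50), 50, 1, dimnames = list(NULL, "x")))
    expect_message(sp <- stability_point(runs, "x"), "skipped")
    expect_equal(sp$n_runs_used, 2)
  })
  expect_error(stability_point(list(matrix(rnorm(5), 5, 1, dimnames = list(NULL, "x"))), "x"),
               "at least 2")
})

test_that("cohort summaries aggregate reached stability points", {
  scan <- tibble::tibble(
    runner_id = c("a", "b", "c"), condition = "level", variable = "cadence_spm",
    stability_point = c(1, 2, 2), reached = TRUE, n_runs_used = 7L)
  s <- stability_summary(scan)
  expect_equal(s$mean, 5 / 3, tolerance = 1e-9)
  expect_equal(s$sd, sd(c(1, 2, 2)))
  expect_equal(s$max, 2)
  expect_equal(s$n_not_reached, 0)

  one <- stability_summary(dplyr::slice(scan, 1))
  expect_equal(one$mean, 1); expect_equal(one$sd, 0); expect_equal(one$max, 1)

  same <- stability_summary(dplyr::mutate(scan, stability_point = 3))
  expect_equal(c(same$mean, same$sd, same$max), c(3, 0, 3))

  nr <- dplyr::mutate(scan, reached = c(TRUE, TRUE, FALSE),
                      stability_point = c(1, 2, NA))
  snr <- stability_summary(nr)
  expect_equal(snr$mean, 1.5)
  expect_equal(snr$n_not_reached, 1)
})

test_that("similarity sweep row counts follow the pair enumeration", {
  mk_records <- function(R, n = 40, shift = 0) {
    withr::with_seed(500 + R, {
      dplyr::bind_rows(lapply(seq_len(R), function(k) {
        rec <- tibble::tibble(runner_id = "r", run_id = k, condition = "level")
        X <- gaitstab:::rmvn(n, c(164, 8.5, 255, 0.28, 8, 10) + shift * k,
                           diag(c(9, .36, 144, .0025, 1.44, 3.24)))
        colnames(X) <- gait_variables()
        dplyr::bind_cols(rec, tibble::as_tibble(X))
      }))
    })
  }
  sw2 <- similarity_sweep(mk_records(2), variables = "cadence_spm",
                          conditions = "level")
  expect_equal(nrow(sw2), 2) # C(2,1) * 1

  sw4 <- similarity_sweep(mk_records(4), variables = "cadence_spm",
                          conditions = "level")
  expect_equal(nrow(sw4), sum(choose(4, 1:3) * (4 - 1:3))) # 28

  sw4p <- similarity_sweep(mk_records(4), variables = "cadence_spm",
                           conditions = "level", pooled_complement = TRUE)
  expect_equal(nrow(sw4p), sum(split_counts(4)$n_pairs))
  expect_equal(sum(is.na(sw4p$test_run)), sum(choose(4, 1:3)))

  ## same-distribution test runs sit near the 95% contour on average
  expect_equal(mean(sw4$pct_similar), 95, tolerance = 4)
  expect_true(all(sw4$n_outside == sw4$n_test - round(sw4$pct_similar * sw4$n_test / 100)))
})
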