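test_that("fit recovers closed-form sample moments", {
  m <- fit_gait_density(c(-1, 0, 1), "x")
  expect_equal(unname(m$mean), 0)
  expect_equal(unname(m$covariance[1, 1]), 1) # n-1 denominator
  expect_equal(m$n_train, 3L)
})

test_that("epsilon approximates the density at the 95% central contour", {
  ## for N(0,1), the 5th percentile of pdf values is the height at +/-1.96
  x <- withr::with_seed(42, rnorm(1e5))
  m <- fit_gait_density(x, "x")
  expect_equal(m$epsilon, dnorm(qnorm(0.975)), tolerance = 0.03)
  expect_lt(abs(m$epsilon - 0.05845), 0.002)
})

test_that("training coverage at epsilon is always in [95%, 100%]", {
  withr::with_seed(9, {
    for (n in c(10, 23, 57, 400)) {
      for (d in c(1, 3)) {
        x <- matrix(rnorm(n * d), ncol = d)
        m <- fit_gait_density(x, paste0("x", seq_len(d)))
        cov_frac <- mean(density_values(m, x) >= m$epsilon)
        expect_gte(cov_frac, 0.95)
        expect_lte(cov_frac, 1)
        expect_gt(m$epsilon, 0)
        expect_lte(m$epsilon, density_values(m, matrix(m$mean, nrow = 1)))
      }
    }
  })
})

test_that("similarity counts points at or above epsilon, ties inclusive", {
  x <- withr::with_seed(3, tibble::tibble(cadence_spm = rnorm(500, 165, 3)))
  m <- fit_gait_density(x, "cadence_spm")
  self <- similarity(m, x)
  expect_gte(self$pct_similar, 95)
  expect_equal(self$n_outside, as.integer(500 - self$n_test * self$pct_similar / 100))

  far <- dplyr::mutate(x, cadence_spm = cadence_spm + 10 * sd(x$cadence_spm))
  expect_lt(similarity(m, far)$pct_similar, 1)

  fresh <- withr::with_seed(4, tibble::tibble(cadence_spm = rnorm(20000, 165, 3)))
  expect_equal(similarity(m, fresh)$pct_similar, 95, tolerance = 0.03)

  expect_warning(und <- similarity(m, x[0, ]), "empty")
  expect_true(is.na(und$pct_similar))
})

test_that("univariate quantile pair is mean +/- 1.959964 SD", {
  m1 <- list(variables = "x", mean = c(x = 0), covariance = matrix(1, 1, 1))
  class(m1) <- "gait_density"
  qp <- quantile_pair(m1)
  expect_equal(qp$q_low, -1.959964, tolerance = 1e-6)
  expect_equal(qp$q_high, 1.959964, tolerance = 1e-6)

  m2 <- list(variables = "x", mean = c(x = 10), covariance = matrix(0.25, 1, 1))
  class(m2) <- "gait_density"
  qp2 <- quantile_pair(m2)
  expect_equal(c(qp2$q_low, qp2$q_high), c(9.02, 10.98), tolerance = 1e-3)

  m0 <- m2; m0$covariance <- matrix(0, 1, 1)
  expect_error(quantile_pair(m0), "degenerate")
})

test_that("multivariate density-height quantiles match a Monte-Carlo oracle", {
  m <- list(variables = c("a", "b"), mean = c(a = 0, b = 0), covariance = diag(2))
  class(m) <- "gait_density"
  qp <- quantile_pair(m)
  expect_equal(qp$scale, "density_height")

  z <- withr::with_seed(11, matrix(rnorm(4e5), ncol = 2))
  heights <- exp(-rowSums(z^2) / 2) / (2 * pi)
  emp <- quantile(heights, c(0.025, 0.975), names = FALSE)
  expect_equal(qp$q_low, emp[1], tolerance = 0.02)
  expect_equal(qp$q_high, emp[2], tolerance = 0.02)
})

test_that("density values agree with the naive quadratic-form oracle", {
  withr::with_seed(8, {
    x <- matrix(rnorm(200 * 4, sd = 2), ncol = 4)
    m <- fit_gait_density(x, paste0("v", 1:4))
    mine <- density_values(m, x)
    oracle <- naive_mvn_pdf(x, m$mean, m$covariance)
    expect_equal(mine, oracle, tolerance = 1e-10)
    ## independent library cross-check
    ref <- mclust::dmvnorm(x, m$mean, m$covariance)
    expect_equal(mine, ref, tolerance = 1e-10)
  })
})

test_that("quantile pair is affine-equivariant and similarity scale-invariant", {
  withr::with_seed(12, {
    x <- rnorm(400, 5, 2)
    test_x <- rnorm(100, 5, 3)
    a <- 3.7; b <- -12
    m1 <- fit_gait_density(x, "x")
    m2 <- fit_gait_density(a * x + b, "x")
    q1 <- quantile_pair(m1); q2 <- quantile_pair(m2)
    expect_equal(q2$q_low, a * q1$q_low + b, tolerance = 1e-10)
    expect_equal(q2$q_high, a * q1$q_high + b, tolerance = 1e-10)
    s1 <- similarity(m1, matrix(test_x, ncol = 1))
    s2 <- similarity(m2, matrix(a * test_x + b, ncol = 1))
    expect_equal(s1$pct_similar, s2$pct_similar)
  })
})

test_that("singular training data triggers logged ridge regularization", {
  x <- withr::with_seed(2, {
    z <- rnorm(50)
    cbind(a = z, b = z, c = rnorm(50)) # rank-deficient
  })
  expect_message(m <- fit_gait_density(x, c("a", "b", "c")), "regularized")
  expect_gt(m$regularization, 0)
  expect_gte(m$coverage, 0.95)

  few <- withr::with_seed(5, matrix(rnorm(4 * 6), ncol = 6,
                                    dimnames = list(NULL, gait_variables())))
  expect_message(m2 <- fit_gait_density(few), "regularized") # n <= d
  expect_gt(m2$regularization, 0)

  expect_error(fit_gait_density(numeric(1), "x"), "at least 2")
})
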