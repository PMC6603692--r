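## shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

## records tibble using the generator's ground-truth condition labels
## (bypasses segmentation where only the downstream statistics are under test)
truth_records <- function(cohort) {
  dplyr::rename(cohort$imu, condition = "condition_true")
}

## a single-segment perfectly flat route with no pauses
flat_route <- function(total_m = 12000, grade = 0, noise = 0) {
  route_spec(
    grade_segments = tibble::tibble(length_m = total_m, grade_pct = grade),
    speed_noise_sd = noise, stop_probability = 0
  )
}

## deterministic runner with chosen noise structure
test_profile <- function(id = "T1", sigma_scale = 1, between = c(1.5, 0.3, 6, 0.02, 0.6, 0.9),
                         effects = NULL, base_speed = 2.4) {
  sds <- c(3, 0.6, 12, 0.05, 1.2, 1.8) * sigma_scale
  sigma <- diag(sds) %*% default_within_cor() %*% diag(sds)
  runner_profile(id, mu = c(164, 8.5, 255, 0.28, 8.0, 10.0), sigma = sigma,
                 between_run_sd = between, condition_effects = effects,
                 base_speed = base_speed)
}

## single-run GPS stream at constant speed over a constant grade
synthetic_gps <- function(total_m = 12000, speed = 2.5, grade = 0,
                          runner_id = "S1", run_id = 1L) {
  n <- ceiling(total_m / speed)
  d <- seq_len(n) * speed
  tibble::tibble(runner_id = runner_id, run_id = run_id, t_s = as.numeric(seq_len(n)),
                 speed_ms = speed, altitude_m = d * grade / 100, dist_km = d / 1000)
}

## naive quadratic-form MVN pdf (independent oracle for density values)
naive_mvn_pdf <- function(x, mu, S) {
  x <- as.matrix(x)
  Sinv <- solve(S)
  q <- apply(x, 1, function(r) drop(t(r - mu) %*% Sinv %*% (r - mu)))
  (2 * pi)^(-length(mu) / 2) * det(S)^(-1 / 2) * exp(-q / 2)
}

## definition-level oracle for the univariate stability point
oracle_stability <- function(runs, thr = 5) {
  qp <- function(x) stats::qnorm(c(0.025, 0.975), mean(x), stats::sd(x))
  R <- length(runs)
  qps <- lapply(seq_len(R), function(N) qp(unlist(runs[seq_len(N)])))
  d <- vapply(seq_len(R - 1), function(N) {
    max(100 * abs(qps[[N + 1]] - qps[[N]]) / abs(qps[[N]]))
  }, numeric(1))
  if (any(d < thr)) which(d < thr)[1] else NA_integer_
}
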