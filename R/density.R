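## log multivariate-normal density via the Cholesky factor of the covariance
mvn_logpdf <- function(x, mean, R) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = length(mean))
  z <- backsolve(R, t(x) - mean, transpose = TRUE)
  q <- colSums(z^2)
  -0.5 * length(mean) * log(2 * pi) - sum(log(diag(R))) - 0.5 * q
}

#' Fit a normal density model with a 95%-coverage threshold
#'
#' Fits a univariate or multivariate normal distribution to training records
#' (sample mean; sample covariance with the n-1 denominator) and derives the
#' density threshold epsilon such that at least `coverage` (95% by default)
#' of the training records have fitted probability density greater than or
#' equal to epsilon. Epsilon is the empirical 5th percentile of the training
#' densities (linear-interpolation percentile); if at small n the
#' interpolated percentile would leave training coverage below the target,
#' epsilon steps down to the largest training density that restores it, so
#' the definitional guarantee always holds.
#'
#' A near-singular covariance (condition number above 1e12, or n <= d) is
#' ridge-regularized by adding a small multiple of the mean diagonal; the
#' added magnitude is recorded in the fitted object and signalled with a
#' message.
#'
#' @param data Tibble/data frame containing the variable columns, or a
#'   numeric matrix/vector.
#' @param variables Character vector of columns to model (default: all of
#'   [gait_variables()] present in `data`; a single name gives the univariate
#'   model).
#' @param coverage Training coverage level for epsilon (default 0.95).
#' @return An object of class `gait_density` with elements `variables`,
#'   `mean`, `covariance`, `epsilon`, `n_train`, `regularization` and
#'   `coverage` (the achieved training coverage).
#' @export
#' @examples
#' x <- tibble::tibble(cadence_spm = rnorm(500, 165, 3))
#' m <- fit_gait_density(x, "cadence_spm")
#' glance(m)
fit_gait_density <- function(data, variables = NULL, coverage = 0.95) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- matrix(data, ncol = 1, dimnames = list(NULL, variables %||% "x"))
  }
  if (is.matrix(data)) {
    if (is.null(colnames(data))) {
      colnames(data) <- variables %||% paste0("x", seq_len(ncol(data)))
    }
    data <- tibble::as_tibble(data)
  }
  variables <- variables %||% intersect(gait_variables(), names(data))
  if (length(variables) == 0) abort("no model variables found in data")
  x <- as_matrix_vars(data, variables)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); d <- ncol(x)
  if (n < 2) abort("density fit needs at least 2 training records")
  mu <- colMeans(x)
  S <- cov(x)
  reg <- 0
  base <- mean(diag(S))
  if (base <= 0) base <- 1e-12
  repeat {
    ok <- tryCatch({
      R <- chol(S + diag(reg, d))
      kappa(S + diag(reg, d)) < 1e12
    }, error = function(e) FALSE)
    if (isTRUE(ok) && n > d) break
    if (isTRUE(ok) && reg > 0) break
    reg <- if (reg == 0) 1e-8 * base else reg * 10
    if (reg > 1e6 * base) abort("covariance could not be regularized")
  }
  if (reg > 0) {
    inform(sprintf("covariance regularized: +%.3g added to the diagonal", reg))
    S <- S + diag(reg, d)
  }
  R <- chol(S)
  dens <- exp(mvn_logpdf(x, mu, R))
  eps <- quantile(dens, 1 - coverage, type = 7, names = FALSE)
  achieved <- mean(dens >= eps)
  if (achieved < coverage) {
    ## step down to the largest order statistic meeting the guarantee
    s <- sort(dens)
    k <- max(which((n - seq_len(n) + 1) / n >= coverage))
    eps <- s[k]
    achieved <- mean(dens >= eps)
  }
  structure(
    list(variables = variables, mean = mu, covariance = S, epsilon = eps,
         n_train = n, regularization = reg, coverage_level = coverage,
         coverage = achieved),
    class = "gait_density"
  )
}

#' Evaluate the fitted probability density at data points
#'
#' @param model A [fit_gait_density()] object.
#' @param data Records with the model's variable columns (or a matrix).
#' @param log Return log densities.
#' @return Numeric vector of (log) density values.
#' @export
density_values <- function(model, data, log = FALSE) {
  stopifnot(inherits(model, "gait_density"))
  x <- if (is.matrix(data)) data[, seq_along(model$variables), drop = FALSE]
       else as_matrix_vars(data, model$variables)
  ld <- mvn_logpdf(x, model$mean, chol(model$covariance))
  if (log) ld else exp(ld)
}

#' Score test records against a fitted density model
#'
#' A test record is "similar" to the training data when its fitted density is
#' greater than or equal to the model's epsilon threshold (ties inclusive).
#' Returns the percentage of similar records and the count falling outside
#' the 95% probability density contour.
#'
#' @param model A [fit_gait_density()] object.
#' @param data Test records.
#' @return One-row tibble: `pct_similar`, `n_test`, `n_outside`.
#' @export
#' @examples
#' x <- tibble::tibble(cadence_spm = rnorm(400, 165, 3))
#' m <- fit_gait_density(x, "cadence_spm")
#' similarity(m, x)
similarity <- function(model, data) {
  stopifnot(inherits(model, "gait_density"))
  dens <- density_values(model, data)
  n <- length(dens)
  if (n == 0) {
    warn("empty test set: similarity is undefined")
    return(tibble::tibble(pct_similar = NA_real_, n_test = 0L, n_outside = NA_integer_))
  }
  n_out <- sum(dens < model$epsilon)
  tibble::tibble(pct_similar = 100 * (n - n_out) / n,
                 n_test = n, n_outside = as.integer(n_out))
}

#' The 2.5/97.5 quantile pair of a fitted density model
#'
#' The pair of quantiles whose run-to-run change drives the stability
#' criterion. For a univariate model these are the conventional quantiles of
#' the fitted normal: mean +/- 1.959964 x SD. For a multivariate model the
#' notion of a variable-space quantile has no canonical analogue, so the pair
#' is defined on the density-height scale: since the Mahalanobis form of a
#' d-variate normal is chi-squared with d degrees of freedom, the p-quantile
#' of the fitted pdf height is
#' `(2*pi)^(-d/2) |Sigma|^(-1/2) exp(-qchisq(1 - p, d)/2)`,
#' evaluated in closed form at p = 0.025 and 0.975.
#'
#' @param model A [fit_gait_density()] object.
#' @param probs Two probabilities (default `c(0.025, 0.975)`).
#' @return One-row tibble: `q_low`, `q_high`, and `scale` ("variable" for
#'   univariate, "density_height" for multivariate).
#' @export
#' @examples
#' m <- fit_gait_density(tibble::tibble(x = rnorm(1000, 10, 0.5)), "x")
#' quantile_pair(m)
quantile_pair <- function(model, probs = c(0.025, 0.975)) {
  stopifnot(inherits(model, "gait_density"), length(probs) == 2)
  probs <- sort(probs)
  d <- length(model$variables)
  if (d == 1) {
    v <- model$covariance[1, 1]
    if (v <= 0) abort("degenerate (zero-variance) fit has no quantile pair")
    q <- qnorm(probs, mean = model$mean[1], sd = sqrt(v))
    return(tibble::tibble(q_low = q[1], q_high = q[2], scale = "variable"))
  }
  logdet <- 2 * sum(log(diag(chol(model$covariance))))
  h <- function(p) exp(-0.5 * d * log(2 * pi) - 0.5 * logdet -
                         0.5 * qchisq(1 - p, df = d))
  tibble::tibble(q_low = h(probs[1]), q_high = h(probs[2]),
                 scale = "density_height")
}

#' @export
print.gait_density <- function(x, ...) {
  cat("<gait_density> d=", length(x$variables), " (",
      paste(x$variables, collapse = ", "), ")\n", sep = "")
  cat("  n_train=", x$n_train, "  epsilon=", format(x$epsilon, digits = 4),
      "  training coverage=", sprintf("%.1f%%", 100 * x$coverage), "\n", sep = "")
  if (x$regularization > 0) {
    cat("  ridge regularization: +", format(x$regularization, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname fit_gait_density
#' @param x A `gait_density` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gait_density <- function(x, ...) {
  tibble::tibble(variable = x$variables, mean = unname(x$mean),
                 sd = sqrt(diag(x$covariance)))
}

#' @rdname fit_gait_density
#' @exportS3Method generics::glance
glance.gait_density <- function(x, ...) {
  tibble::tibble(d = length(x$variables), n_train = x$n_train,
                 epsilon = x$epsilon, training_coverage = 100 * x$coverage,
                 regularization = x$regularization)
}
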