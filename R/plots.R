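#' Plot a fitted density model and its epsilon contour
#'
#' For a univariate model: the fitted normal curve with the epsilon density
#' threshold and the 2.5/97.5 quantile pair marked. For a multivariate
#' model: the implied distribution of fitted density heights (via the
#' chi-squared Mahalanobis form) with epsilon and the density-height
#' quantile pair.
#'
#' @param object A [fit_gait_density()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gait_density <- function(object, ...) {
  d <- length(object$variables)
  if (d == 1) {
    mu <- object$mean[1]; s <- sqrt(object$covariance[1, 1])
    qp <- quantile_pair(object)
    df <- tibble::tibble(x = seq(mu - 4 * s, mu + 4 * s, length.out = 400))
    df$dens <- stats::dnorm(df$x, mu, s)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$dens)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::geom_hline(yintercept = object$epsilon, linetype = 2,
                          colour = "firebrick") +
      ggplot2::geom_vline(xintercept = c(qp$q_low, qp$q_high),
                          linetype = 3, colour = "grey40") +
      ggplot2::labs(x = object$variables, y = "fitted density",
                    title = "Fitted normal with epsilon threshold",
                    subtitle = sprintf("epsilon = %.4g; dotted: 2.5/97.5 quantiles",
                                       object$epsilon)) +
      ggplot2::theme_minimal()
  } else {
    logdet <- 2 * sum(log(diag(chol(object$covariance))))
    q <- seq(0.001, qchisq(0.999, d), length.out = 400)
    h <- exp(-0.5 * d * log(2 * pi) - 0.5 * logdet - 0.5 * q)
    df <- tibble::tibble(height = h, dens = stats::dchisq(q, d))
    qp <- quantile_pair(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$height, y = .data$dens)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::geom_vline(xintercept = object$epsilon, linetype = 2,
                          colour = "firebrick") +
      ggplot2::geom_vline(xintercept = c(qp$q_low, qp$q_high),
                          linetype = 3, colour = "grey40") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "pdf height (log scale)", y = "implied density",
                    title = sprintf("Density-height distribution (d = %d)", d)) +
      ggplot2::theme_minimal()
  }
}

#' Plot a stability trace: quantile change against training-set size
#'
#' Shows the per-addition change (%) of the 2.5 and 97.5 quantiles as runs
#' accumulate, the stability threshold, and the stability point when
#' reached.
#'
#' @param object A [stability_point()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stability_point <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace[-1, c("n_train", "delta_low", "delta_high")],
                            -"n_train", names_to = "quantile",
                            values_to = "delta")
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$n_train - 1,
                                        y = .data$delta,
                                        colour = .data$quantile)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "runs in training set (N) before addition",
                  y = "quantile change on adding run N+1 (%)",
                  title = "Quantile-change stability criterion") +
    ggplot2::theme_minimal()
  if (object$reached) {
    p <- p + ggplot2::geom_vline(xintercept = object$stability_point,
                                 colour = "forestgreen", linetype = 3)
  }
  p
}

#' Plot cohort stability summaries
#'
#' Mean +/- SD stability points per variable and condition, with the
#' cohort maximum (the "runs needed" answer) marked.
#'
#' @param summary A [stability_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_stability_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$variable, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$max), shape = 4, size = 3,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "stability point (runs)",
                  title = "Runs needed for a stable gait pattern",
                  subtitle = "points: cohort mean +/- SD; crosses: cohort maximum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of crossover correlations
#'
#' Table-style matrix of Pearson r per (train condition, test condition)
#' cell, faceted by variable, with agreement bands as labels.
#'
#' @param correlations A [crossover_correlations()] tibble.
#' @return A ggplot object.
#' @export
plot_crossover_matrix <- function(correlations) {
  ggplot2::ggplot(correlations,
                  ggplot2::aes(x = .data$test_condition,
                               y = .data$train_condition,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~variable) +
    ggplot2::labs(x = "test condition", y = "train condition",
                  title = "Crossover condition correlations") +
    ggplot2::theme_minimal()
}
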