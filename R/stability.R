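#' Enumerate unique training/testing splits of a runner's runs
#'
#' All `choose(R, N)` unique training subsets of size `N`, in deterministic
#' lexicographic order; every run left out of a training set is a separate
#' test set, so each subset contributes `R - N` train/test pairs.
#'
#' @param run_ids Vector of run identifiers (length R).
#' @param n_train Training-set size N, `1 <= N <= R`.
#' @return Tibble with one row per unique training set: `n_train`,
#'   `split_id`, list-columns `train` and `test`.
#' @export
#' @examples
#' enumerate_splits(1:4, 2)
enumerate_splits <- function(run_ids, n_train) {
  R <- length(run_ids)
  if (n_train < 1 || n_train > R) {
    abort(sprintf("n_train must be between 1 and %d", R))
  }
  run_ids <- sort(run_ids)
  sets <- combn(run_ids, n_train, simplify = FALSE)
  tibble::tibble(
    n_train = n_train,
    split_id = seq_along(sets),
    train = sets,
    test = lapply(sets, function(s) setdiff(run_ids, s))
  )
}

#' Training/testing enumeration audit table
#'
#' For R runs and every training-set size N: the number of unique training
#' sets `choose(R, N)` and the number of training/testing dataset pairs.
#' The published seven-run accounting (49, 126, 175, 140, 63, 14, 0) counts,
#' for each unique training set, each left-out run as a separate testing
#' dataset plus the pooled complement as one further testing dataset —
#' `choose(R, N) * (R - N + 1)` for N < R — even though a strict
#' leave-one-out reading gives `choose(R, N) * (R - N)`. The default
#' reproduces the published accounting; set `pooled_complement = FALSE` for
#' the strict count.
#'
#' @param n_runs Number of runs R.
#' @param pooled_complement Count the pooled complement of each training set
#'   as an additional testing dataset.
#' @return Tibble with `n_train`, `n_sets`, `n_pairs`.
#' @export
split_counts <- function(n_runs = 7, pooled_complement = TRUE) {
  n <- seq_len(n_runs)
  per_set <- (n_runs - n) + if (pooled_complement) as.numeric(n < n_runs) else 0
  tibble::tibble(
    n_train = n,
    n_sets = choose(n_runs, n),
    n_pairs = choose(n_runs, n) * per_set
  )
}

#' Relative change between two quantile pairs
#'
#' The percentage change of each quantile when a run is added:
#' `100 * |next - prev| / |prev|`. When a previous quantile is numerically
#' zero (|prev| < 1e-12) the relative change is undefined; the delta is then
#' computed on an absolute scale, `100 * |next - prev| / abs_scale`, and
#' flagged.
#'
#' @param prev,next_ Quantile pairs ([quantile_pair()] rows, or numeric
#'   length-2 vectors `(q_low, q_high)`).
#' @param abs_scale Positive scale for the near-zero fallback (for univariate
#'   models, the fitted SD; for density-height pairs, the previous `q_high`).
#' @return One-row tibble: `delta_low`, `delta_high` (%), and logical
#'   `absolute_low`, `absolute_high` marking where the fallback was used.
#' @export
#' @examples
#' quantile_change(c(-2, 100), c(-2.2, 104))
quantile_change <- function(prev, next_, abs_scale = NULL) {
  as_pair <- function(q) {
    if (is.data.frame(q)) c(q$q_low[1], q$q_high[1]) else as.numeric(q[1:2])
  }
  p <- as_pair(prev); n <- as_pair(next_)
  absolute <- abs(p) < 1e-12
  delta <- numeric(2)
  delta[!absolute] <- 100 * abs(n[!absolute] - p[!absolute]) / abs(p[!absolute])
  if (any(absolute)) {
    if (is.null(abs_scale) || !is.finite(abs_scale) || abs_scale <= 0) {
      warn("near-zero previous quantile with no abs_scale; delta set to NA")
      delta[absolute] <- NA_real_
    } else {
      delta[absolute] <- 100 * abs(n[absolute] - p[absolute]) / abs_scale
    }
  }
  tibble::tibble(delta_low = delta[1], delta_high = delta[2],
                 absolute_low = absolute[1], absolute_high = absolute[2])
}

## pool a runner's records for one condition into per-run matrices,
## ordered chronologically by run id
run_matrices <- function(records, condition, variables) {
  rec <- condition_records(records, condition)
  if (nrow(rec) == 0) return(list())
  rec <- rec[order(rec$run_id), , drop = FALSE]
  lapply(split(as_matrix_vars(rec, variables), rec$run_id), function(m) {
    matrix(m, ncol = length(variables), dimnames = list(NULL, variables))
  })
}

#' Stability point of an accumulating sequence of runs
#'
#' Fits the density model on the pooled first N runs for N = 1, 2, ...,
#' tracks the 2.5/97.5 quantile pair, and declares stability at the smallest
#' N for which adding run N+1 changes both quantiles by less than
#' `threshold` percent (first crossing). With `sustained = TRUE`, every
#' later addition must also stay under the threshold. Runs with no records
#' are skipped (with a message) and the remaining runs re-indexed.
#'
#' @param run_data List of per-run record sets in chronological order (each a
#'   tibble or matrix with the model variables), e.g. from one condition of a
#'   segmented cohort.
#' @param variables Variables of the density model (one name for univariate;
#'   several for multivariate).
#' @param threshold Stability threshold, percent (default 5).
#' @param sustained Require all subsequent additions to stay under threshold.
#' @param quantile_fun Quantile functional applied to each fitted model
#'   (default [quantile_pair()]); pluggable because the multivariate quantile
#'   definition is a modelling choice.
#' @return An object of class `stability_point`: list with
#'   `stability_point` (integer, or `NA` when not reached), `reached`,
#'   `n_runs_used`, and `trace` (tibble of `n_train`, `q_low`, `q_high`,
#'   `delta_low`, `delta_high`).
#' @export
stability_point <- function(run_data, variables, threshold = 5,
                            sustained = FALSE, quantile_fun = quantile_pair) {
  sizes <- vapply(run_data, NROW, integer(1))
  if (any(sizes == 0)) {
    inform(sprintf("%d empty run(s) skipped and runs re-indexed", sum(sizes == 0)))
    run_data <- run_data[sizes > 0]
  }
  R <- length(run_data)
  if (R < 2) abort("stability_point() needs at least 2 runs with data")
  mats <- lapply(run_data, function(d) {
    if (is.matrix(d)) d[, variables, drop = FALSE] else as_matrix_vars(d, variables)
  })
  qp <- vector("list", R)
  sds <- numeric(R)
  pooled <- NULL
  for (N in seq_len(R)) {
    pooled <- rbind(pooled, mats[[N]])
    fit <- fit_gait_density(pooled, variables)
    qp[[N]] <- quantile_fun(fit)
    sds[N] <- if (length(variables) == 1) sqrt(fit$covariance[1, 1]) else qp[[N]]$q_high
  }
  deltas <- purrr::map_dfr(seq_len(R - 1), function(N) {
    quantile_change(qp[[N]], qp[[N + 1]], abs_scale = sds[N])
  })
  under <- deltas$delta_low < threshold & deltas$delta_high < threshold
  under[is.na(under)] <- FALSE
  sp <- if (sustained) {
    ok <- rev(cumprod(rev(under))) == 1
    if (any(ok)) which(ok)[1] else NA_integer_
  } else {
    if (any(under)) which(under)[1] else NA_integer_
  }
  trace <- dplyr::bind_rows(lapply(qp, function(q) q[, c("q_low", "q_high")]))
  trace <- tibble::tibble(n_train = seq_len(R), trace,
                          delta_low = c(NA, deltas$delta_low),
                          delta_high = c(NA, deltas$delta_high))
  structure(
    list(stability_point = as.integer(sp), reached = !is.na(sp),
         n_runs_used = R, threshold = threshold, variables = variables,
         trace = trace),
    class = "stability_point"
  )
}

#' @export
print.stability_point <- function(x, ...) {
  cat("<stability_point> ",
      if (x$reached) paste0("reached at N = ", x$stability_point)
      else "not reached",
      " (", x$n_runs_used, " runs, <", x$threshold, "% rule)\n", sep = "")
  invisible(x)
}

#' @rdname stability_point
#' @param x A `stability_point` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.stability_point <- function(x, ...) x$trace

#' Stability points for every runner, variable and condition
#'
#' Applies [stability_point()] over a segmented cohort: for each runner, each
#' elevation condition, and each variable spec (the six univariate models and
#' the six-variable multivariate model), using runs in chronological order.
#' Cells with fewer than two non-empty runs are dropped with a message.
#'
#' @param seg A `gait_segmentation` (or its `records` tibble).
#' @param variables `"all"` (six univariate + multivariate) or a character
#'   vector of variable names, optionally including `"multivariate"`.
#' @param conditions Conditions to scan.
#' @param threshold Stability threshold, percent.
#' @param sustained Passed to [stability_point()].
#' @param mode `"chronological"` (the study's accumulation order) or
#'   `"permuted"`: average the stability point over `n_perm` seeded random
#'   run orderings (sensitivity analysis).
#' @param n_perm,seed Permutation count and seed for `mode = "permuted"`.
#' @return Tibble: `runner_id`, `condition`, `variable`, `stability_point`
#'   (mean over orderings when permuted), `reached`, `n_runs_used`.
#' @export
stability_scan <- function(seg, variables = "all",
                           conditions = gait_conditions(), threshold = 5,
                           sustained = FALSE,
                           mode = c("chronological", "permuted"),
                           n_perm = 20, seed = 1) {
  mode <- match.arg(mode)
  records <- if (inherits(seg, "gait_segmentation")) seg$records else seg
  specs <- variable_specs(variables)
  grid <- tidyr::expand_grid(runner_id = unique(records$runner_id),
                             condition = conditions,
                             variable = names(specs))
  one_cell <- function(runner_id, condition, variable) {
    rec <- dplyr::filter(records, .data$runner_id == !!runner_id)
    mats <- run_matrices(rec, condition, specs[[variable]])
    mats <- mats[vapply(mats, nrow, integer(1)) > 1]
    if (length(mats) < 2) {
      return(tibble::tibble(runner_id = runner_id, condition = condition,
                            variable = variable, stability_point = NA_real_,
                            reached = FALSE, n_runs_used = length(mats)))
    }
    run_one <- function(order_idx) {
      suppressMessages(
        stability_point(mats[order_idx], specs[[variable]],
                        threshold = threshold, sustained = sustained)
      )
    }
    if (mode == "chronological") {
      sp <- run_one(seq_along(mats))
      tibble::tibble(runner_id = runner_id, condition = condition,
                     variable = variable,
                     stability_point = as.numeric(sp$stability_point),
                     reached = sp$reached, n_runs_used = sp$n_runs_used)
    } else {
      pts <- with_seed(derive_seed(seed, 3L, match(runner_id, unique(records$runner_id))), {
        vapply(seq_len(n_perm), function(i) {
          as.numeric(run_one(sample(seq_along(mats)))$stability_point)
        }, numeric(1))
      })
      tibble::tibble(runner_id = runner_id, condition = condition,
                     variable = variable,
                     stability_point = mean(pts, na.rm = TRUE),
                     reached = any(!is.na(pts)), n_runs_used = length(mats))
    }
  }
  out <- purrr::pmap_dfr(grid, one_cell)
  dropped <- sum(out$n_runs_used < 2)
  if (dropped > 0) {
    inform(sprintf("%d runner/condition/variable cell(s) had <2 usable runs", dropped))
  }
  dplyr::filter(out, .data$n_runs_used >= 2)
}

#' Summarise stability points across runners
#'
#' Per condition and variable: mean, SD and maximum stability point over
#' runners that reached stability, plus the count that did not. The maximum
#' row is the cohort-level answer to "how many runs are needed".
#'
#' @param scan A [stability_scan()] result.
#' @return Tibble: `condition`, `variable`, `n`, `mean`, `sd`, `max`,
#'   `n_not_reached`.
#' @export
stability_summary <- function(scan) {
  if (nrow(scan) == 0) {
    warn("empty stability scan; nothing to summarise")
    return(tibble::tibble())
  }
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  out <- dplyr::summarise(
    dplyr::group_by(scan, .data$condition, .data$variable),
    n = sum(.data$reached),
    mean = mean(.data$stability_point[.data$reached]),
    sd = sd0(.data$stability_point[.data$reached]),
    max = if (any(.data$reached)) max(.data$stability_point[.data$reached]) else NA_real_,
    n_not_reached = sum(!.data$reached),
    .groups = "drop"
  )
  if (any(out$n == 0)) warn("some cells have no runner reaching stability")
  out
}

#' Leave-one-out similarity sweep over all training/testing splits
#'
#' For every training-set size N, every unique training subset and every
#' left-out test run: fit the density model on the pooled training runs and
#' record the percentage of test-run records inside the 95% density contour.
#' With R runs all populated, a runner/condition/variable cell contributes
#' `sum(choose(R, N) * (R - N))` rows, or `sum(choose(R, N) * (R - N + 1))`
#' (567 for R = 7, the published pair accounting) when the pooled complement
#' of each training set is also scored as one further testing dataset
#' (`test_run = NA` rows). Descriptive: the stability decision itself uses
#' only the quantile-change rule.
#'
#' @param seg A `gait_segmentation` or records tibble.
#' @param variables,conditions As in [stability_scan()].
#' @param n_train Training sizes to sweep (default all `1..R-1`).
#' @param pooled_complement Also score each training set against its pooled
#'   complement (the published pair accounting).
#' @return Tibble: `runner_id`, `condition`, `variable`, `n_train`,
#'   `split_id`, `test_run`, `pct_similar`, `n_test`, `n_outside`.
#' @export
similarity_sweep <- function(seg, variables = "all",
                             conditions = gait_conditions(), n_train = NULL,
                             pooled_complement = FALSE) {
  records <- if (inherits(seg, "gait_segmentation")) seg$records else seg
  specs <- variable_specs(variables)
  runners <- unique(records$runner_id)
  out <- vector("list", 0)
  for (rid in runners) {
    rec <- dplyr::filter(records, .data$runner_id == !!rid)
    for (cond in conditions) {
      mats_all <- run_matrices(rec, cond, gait_variables())
      mats_all <- mats_all[vapply(mats_all, nrow, integer(1)) > 1]
      R <- length(mats_all)
      if (R < 2) next
      run_ids <- as.integer(names(mats_all))
      sizes <- n_train %||% seq_len(R - 1)
      sizes <- sizes[sizes >= 1 & sizes < R]
      for (vn in names(specs)) {
        vars <- specs[[vn]]
        mats <- lapply(mats_all, function(m) m[, vars, drop = FALSE])
        for (N in sizes) {
          splits <- enumerate_splits(run_ids, N)
          for (s in seq_len(nrow(splits))) {
            tr_idx <- match(splits$train[[s]], run_ids)
            fit <- fit_gait_density(do.call(rbind, mats[tr_idx]), vars)
            for (te in splits$test[[s]]) {
              sc <- similarity(fit, mats[[match(te, run_ids)]])
              out[[length(out) + 1L]] <- tibble::tibble(
                runner_id = rid, condition = cond, variable = vn,
                n_train = N, split_id = s, test_run = te,
                pct_similar = sc$pct_similar, n_test = sc$n_test,
                n_outside = sc$n_outside)
            }
            if (pooled_complement) {
              te_idx <- match(splits$test[[s]], run_ids)
              sc <- similarity(fit, do.call(rbind, mats[te_idx]))
              out[[length(out) + 1L]] <- tibble::tibble(
                runner_id = rid, condition = cond, variable = vn,
                n_train = N, split_id = s, test_run = NA_integer_,
                pct_similar = sc$pct_similar, n_test = sc$n_test,
                n_outside = sc$n_outside)
            }
          }
        }
      }
    }
  }
  dplyr::bind_rows(out)
}
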