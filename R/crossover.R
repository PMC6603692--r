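#' Random five-train / two-test split of a runner's runs
#'
#' Uniformly samples the training subset (size `n_train`, default 5 of 7);
#' the remaining runs are the test runs. Seeded and reproducible.
#'
#' @param run_ids Vector of run identifiers.
#' @param seed Integer seed.
#' @param n_train Training-set size. When left `NULL`, fewer than 7 runs is
#'   an error (the study design uses 5 + 2 of 7); pass an explicit size to
#'   override.
#' @return List with `train` and `test` id vectors.
#' @export
crossover_split <- function(run_ids, seed, n_train = NULL) {
  R <- length(run_ids)
  if (is.null(n_train)) {
    if (R < 7) abort("crossover_split() expects >= 7 runs; pass n_train to override")
    n_train <- 5L
  }
  if (n_train < 1 || n_train >= R) abort("n_train must leave at least one test run")
  with_seed(seed, {
    train <- sort(sample(run_ids, n_train))
    list(train = train, test = sort(setdiff(run_ids, train)))
  })
}

#' Pearson product-moment correlation with validity checks
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance; pairs with missing values are dropped.
#' @return Correlation coefficient, or `NA` (with a warning) when undefined.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 4, 7))
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    warn("pearson_r() needs at least 3 complete pairs")
    return(NA_real_)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("pearson_r() undefined for zero-variance input")
    return(NA_real_)
  }
  cor(x, y)
}

#' Classify a correlation coefficient into agreement bands
#'
#' Bands: poor (r < 0.60), good (0.60 <= r <= 0.80), very good
#' (0.80 < r <= 0.95), excellent (r > 0.95). The published band edges
#' (0.61-0.80, 0.81-0.95) leave sub-0.01 gaps; the bands are closed into
#' contiguous intervals at 0.60, 0.80 and 0.95.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return Character vector of bands.
#' @export
#' @examples
#' classify_r(c(0.98, 0.70, 0.50))
classify_r <- function(r) {
  out <- rep(NA_character_, length(r))
  out[r < 0.60] <- "poor"
  out[r >= 0.60 & r <= 0.80] <- "good"
  out[r > 0.80 & r <= 0.95] <- "very good"
  out[r > 0.95] <- "excellent"
  out
}

#' Crossover condition analysis: out-of-contour counts across conditions
#'
#' For each runner, randomly designates five training and two test runs; for
#' each train condition and variable spec, fits the density model on the
#' pooled training-run records of that condition and counts the test-run
#' records of every test condition falling outside the 95% density contour
#' (below epsilon). Also computes, per runner, condition and variable, the
#' reference counts of the original within-condition analysis at the
#' five-run point: the mean `n_outside` over all `choose(R, 5)` leave-out
#' splits with five training runs.
#'
#' @param seg A `gait_segmentation` or records tibble.
#' @param variables As in [stability_scan()].
#' @param seed Integer master seed for the per-runner random splits.
#' @param n_train Training runs per split (`NULL` = study default of 5).
#' @param conditions Conditions crossed.
#' @return An object of class `gait_crossover`: list of tibbles `counts`
#'   (`runner_id`, `variable`, `train_condition`, `test_condition`,
#'   `n_outside`, `n_test`) and `reference` (`runner_id`, `variable`,
#'   `condition`, `ref_outside`).
#' @export
crossover_counts <- function(seg, variables = "all", seed = 1,
                             n_train = NULL,
                             conditions = gait_conditions()) {
  records <- if (inherits(seg, "gait_segmentation")) seg$records else seg
  specs <- variable_specs(variables)
  runners <- unique(records$runner_id)
  counts <- list(); reference <- list()
  for (ri in seq_along(runners)) {
    rid <- runners[ri]
    rec <- dplyr::filter(records, .data$runner_id == !!rid)
    run_ids <- sort(unique(rec$run_id))
    nt <- n_train %||% if (length(run_ids) >= 7) 5L else
      abort("runner has <7 runs; pass n_train to override")
    sp <- crossover_split(run_ids, seed = derive_seed(seed, 4L, ri),
                          n_train = nt)
    mats <- lapply(stats::setNames(nm = conditions), function(cond) {
      run_matrices(rec, cond, gait_variables())
    })
    for (vn in names(specs)) {
      vars <- specs[[vn]]
      for (tc in conditions) {
        m_tr <- mats[[tc]][as.character(sp$train)]
        m_tr <- m_tr[!vapply(m_tr, is.null, logical(1))]
        train_x <- do.call(rbind, lapply(m_tr, function(m) m[, vars, drop = FALSE]))
        fit <- if (!is.null(train_x) && nrow(train_x) > 1) {
          fit_gait_density(train_x, vars)
        }
        for (sc_cond in conditions) {
          m_te <- mats[[sc_cond]][as.character(sp$test)]
          m_te <- m_te[!vapply(m_te, is.null, logical(1))]
          test_x <- do.call(rbind, lapply(m_te, function(m) m[, vars, drop = FALSE]))
          res <- if (is.null(fit) || is.null(test_x) || nrow(test_x) == 0) {
            tibble::tibble(pct_similar = NA_real_, n_test = 0L,
                           n_outside = NA_integer_)
          } else similarity(fit, test_x)
          counts[[length(counts) + 1L]] <- tibble::tibble(
            runner_id = rid, variable = vn, train_condition = tc,
            test_condition = sc_cond, n_outside = res$n_outside,
            n_test = res$n_test)
        }
      }
      ## original analysis at the five-run point: mean over all C(R, nt)
      ## leave-out splits within each condition
      for (cond in conditions) {
        mc <- mats[[cond]]
        mc <- mc[vapply(mc, nrow, integer(1)) > 1]
        if (length(mc) <= nt) {
          reference[[length(reference) + 1L]] <- tibble::tibble(
            runner_id = rid, variable = vn, condition = cond,
            ref_outside = NA_real_)
          next
        }
        ids <- as.integer(names(mc))
        splits <- enumerate_splits(ids, nt)
        outs <- numeric(0)
        for (s in seq_len(nrow(splits))) {
          tr <- lapply(mc[match(splits$train[[s]], ids)],
                       function(m) m[, vars, drop = FALSE])
          fit_s <- fit_gait_density(do.call(rbind, tr), vars)
          for (te in splits$test[[s]]) {
            outs <- c(outs, similarity(fit_s, mc[[match(te, ids)]][, vars, drop = FALSE])$n_outside)
          }
        }
        reference[[length(reference) + 1L]] <- tibble::tibble(
          runner_id = rid, variable = vn, condition = cond,
          ref_outside = mean(outs))
      }
    }
  }
  structure(
    list(counts = dplyr::bind_rows(counts),
         reference = dplyr::bind_rows(reference), seed = seed),
    class = "gait_crossover"
  )
}

#' @export
print.gait_crossover <- function(x, ...) {
  cat("<gait_crossover> ", dplyr::n_distinct(x$counts$runner_id),
      " runners, ", dplyr::n_distinct(x$counts$variable), " variable specs",
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Correlate crossover counts against the original analysis
#'
#' For every variable and (train condition, test condition) pair: the
#' Pearson correlation, across runners, between the crossover out-of-contour
#' counts and the original within-condition five-run reference counts of the
#' test condition, banded per [classify_r()]. Same-condition cells compare
#' two five-run analyses of the same condition and are expected to correlate
#' near 1; cross-condition cells degrade with condition-specific gait shifts.
#'
#' @param xo A [crossover_counts()] result.
#' @param reference_condition Which cell condition indexes the reference
#'   counts: `"test"` (default) or `"train"`.
#' @return Tibble: `variable`, `train_condition`, `test_condition`, `r`,
#'   `band`, `n_runners`.
#' @export
crossover_correlations <- function(xo, reference_condition = c("test", "train")) {
  stopifnot(inherits(xo, "gait_crossover"))
  reference_condition <- match.arg(reference_condition)
  joined <- dplyr::left_join(
    xo$counts,
    dplyr::rename(xo$reference, ref_condition = "condition"),
    by = dplyr::join_by("runner_id", "variable",
                        !!rlang::sym(paste0(reference_condition, "_condition")) ==
                          "ref_condition")
  )
  dplyr::summarise(
    dplyr::group_by(joined, .data$variable, .data$train_condition,
                    .data$test_condition),
    n_runners = sum(is.finite(.data$n_outside) & is.finite(.data$ref_outside)),
    r = suppressWarnings(pearson_r(.data$n_outside, .data$ref_outside)),
    .groups = "drop"
  ) |>
    dplyr::mutate(band = classify_r(.data$r))
}
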