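#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation; the p-value comes from the t transform with
#' `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return list with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    cfni_stop("need equal-length vectors with at least 3 observations",
              "cfni_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    cfni_stop("correlation undefined: zero variance", "cfni_validation_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Split carts into HEI quintiles
#'
#' Rank-based split: carts are stably sorted by score (ties keep input
#' order), group sizes are as equal as possible with remainders assigned to
#' the lowest-index quintiles, and label 1 holds the lowest scores.
#'
#' @param scores numeric vector, length `>= 5`.
#' @return integer vector of labels 1-5 aligned with `scores`.
#' @export
assign_quintiles <- function(scores) {
  n <- length(scores)
  if (n < 5) cfni_stop("need at least 5 observations", "cfni_partition_error")
  sizes <- rep(n %/% 5, 5) + as.integer(seq_len(5) <= n %% 5)
  labels <- integer(n)
  labels[order(scores)] <- rep(seq_len(5), sizes)  # order() is stable
  labels
}

#' Tier-composition profile over HEI quintiles
#'
#' Per-quintile counts and mean tier percentages, plus a linear trend test
#' per tier variable: OLS of the percentage on the quintile index treated as
#' numeric 1-5, with a two-sided t test on the slope.
#'
#' @param summaries per-cart tier summaries (`pct_green`, `pct_yellow`,
#'   `pct_red`).
#' @param labels quintile labels aligned with `summaries` (from
#'   [assign_quintiles()]).
#' @return list with `table` (per-quintile counts and means) and `trend`
#'   (slope and p per tier variable).
#' @export
quintile_profile <- function(summaries, labels) {
  if (nrow(summaries) != length(labels)) {
    cfni_stop("labels not aligned with summaries", "cfni_validation_error")
  }
  if (length(unique(labels)) < 5) {
    cfni_stop("empty quintile", "cfni_partition_error")
  }
  tiers <- c("pct_green", "pct_yellow", "pct_red")
  tab <- data.frame(quintile = 1:5,
                    n = as.integer(table(factor(labels, levels = 1:5))))
  for (tv in tiers) {
    tab[[paste0("mean_", tv)]] <-
      vapply(1:5, function(q) mean(summaries[[tv]][labels == q]), numeric(1))
  }
  trend <- lapply(tiers, function(tv) {
    y <- summaries[[tv]]
    if (stats::sd(y) == 0) return(list(slope = 0, p = 1))
    # exact trends give zero residual variance; summary.lm warns but the
    # slope and its Inf t-statistic are the right degenerate answer
    fit <- suppressWarnings(stats::summary.lm(stats::lm(y ~ labels)))
    slope <- fit$coefficients["labels", "Estimate"]
    se <- fit$coefficients["labels", "Std. Error"]
    p <- if (se == 0) as.numeric(slope == 0) else
      fit$coefficients["labels", "Pr(>|t|)"]
    list(slope = slope, p = p)
  })
  names(trend) <- tiers
  list(table = tab, trend = trend)
}

#' k-fold cross-validated index-vs-HEI correlation
#'
#' The headline validation: carts are randomly partitioned into `k`
#' equal-as-possible folds (seeded); for each fold the chosen weight model is
#' fitted on the other folds, transformed into an index formula, used to score
#' the held-out carts, and the Pearson correlation between held-out index and
#' held-out HEI is recorded. The mean of the `k` correlations estimates the
#' index-HEI correlation in a new sample.
#'
#' @param summaries per-cart tier summaries.
#' @param hei per-cart HEI scores (data.frame with `cart_id`/`hei_total` or a
#'   vector aligned with `summaries`).
#' @param method model variant, see [fit_index_model()].
#' @param k number of folds (default 5).
#' @param seed integer seed for the partition.
#' @param ... passed to the model fitter.
#' @return object of class `cfni_cv`: `fold_sizes`, `fold_correlations`,
#'   `mean_r`, `sd_r` (sample SD over folds), `method`, `seed`.
#' @export
kfold_cv_correlation <- function(summaries, hei, method = "model1_ridge_ic",
                                 k = 5, seed = 20220921, ...) {
  m <- model_frame(summaries, hei)
  n <- nrow(m)
  if (n < 2 * k) cfni_stop("need n >= 2k carts", "cfni_validation_error")
  assign <- fold_assignment(n, k, seed)
  fold_sizes <- tabulate(assign, k)
  rs <- numeric(k)
  for (f in seq_len(k)) {
    train <- m[assign != f, , drop = FALSE]
    test <- m[assign == f, , drop = FALSE]
    fit <- fit_index_model(train, train$hei_total, method = method, ...)
    formula <- to_index_formula(fit)
    test_sum <- data.frame(pct_green = test$pct_green,
                           pct_yellow = 100 - test$pct_green - test$pct_red,
                           pct_red = test$pct_red)
    idx <- cfni_score(formula, test_sum)
    if (stats::sd(idx) == 0 || stats::sd(test$hei_total) == 0) {
      cfni_stop(sprintf("fold %d has zero variance in index or HEI", f),
                "cfni_fold_error")
    }
    rs[f] <- pearson_r(idx, test$hei_total)$r
  }
  structure(list(fold_sizes = fold_sizes, fold_correlations = rs,
                 mean_r = mean(rs), sd_r = stats::sd(rs),
                 method = method, seed = seed),
            class = "cfni_cv")
}

#' @export
print.cfni_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV correlation [%s]\n", length(x$fold_correlations),
              x$method))
  for (f in seq_along(x$fold_correlations)) {
    cat(sprintf("  fold %d (n = %d): r = %.4f\n", f, x$fold_sizes[f],
                x$fold_correlations[f]))
  }
  cat(sprintf("  mean = %.4f, SD = %.4f\n", x$mean_r, x$sd_r))
  invisible(x)
}
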