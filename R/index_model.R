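#' @title Weight learning: predicting HEI from tier composition
#' @description
#' Three models predict a cart's HEI-2015 total from its percentage of green
#' and percentage of red food (the percentage of yellow is omitted as the
#' collinear remainder): ridge regression with the penalty chosen by an
#' information criterion (model 1), ridge with the penalty chosen by inner
#' cross-validation (model 2), and ordinary least squares (model 3). The
#' fitted plane is then rewritten as a three-tier weighted sum rescaled to
#' 0-100 — the Charitable Food Nutrition Index.
#' @name index_model
NULL

new_cfni_fit <- function(method, constant, coef_green, coef_red, penalty,
                         diagnostics = NULL) {
  structure(list(method = method, constant = constant,
                 coef_green = coef_green, coef_red = coef_red,
                 penalty = penalty, diagnostics = diagnostics),
            class = "cfni_fit")
}

#' @export
print.cfni_fit <- function(x, ...) {
  cat(sprintf("CFNI weight model [%s]\n", x$method))
  cat(sprintf("  HEI ~ %.4f + %.4f * pct_green %+.4f * pct_red\n",
              x$constant, x$coef_green, x$coef_red))
  if (x$penalty > 0) cat(sprintf("  ridge penalty lambda = %g\n", x$penalty))
  invisible(x)
}

# Align tier summaries with HEI scores by cart_id and return the model frame.
model_frame <- function(summaries, hei) {
  if (is.data.frame(hei)) {
    m <- merge(summaries[c("cart_id", "pct_green", "pct_red")],
               hei[c("cart_id", "hei_total")], by = "cart_id")
    if (nrow(m) < nrow(summaries)) {
      cfni_stop("cart_ids of tier summaries and HEI scores do not match",
                "cfni_validation_error")
    }
  } else {
    if (length(hei) != nrow(summaries)) {
      cfni_stop("HEI vector length does not match tier summaries",
                "cfni_validation_error")
    }
    m <- data.frame(cart_id = summaries$cart_id,
                    pct_green = summaries$pct_green,
                    pct_red = summaries$pct_red, hei_total = hei)
  }
  m
}

#' Ordinary least squares fit (model 3)
#'
#' Unpenalised least-squares regression of HEI on %green and %red with an
#' intercept, via [stats::lm()].
#'
#' @param summaries per-cart tier summaries ([summarize_carts()] output or any
#'   data.frame with `cart_id`, `pct_green`, `pct_red`).
#' @param hei per-cart HEI scores: a data.frame with `cart_id` and `hei_total`
#'   (matched by id) or a numeric vector aligned with `summaries`.
#' @return a `cfni_fit`.
#' @export
fit_ols <- function(summaries, hei) {
  m <- model_frame(summaries, hei)
  if (nrow(m) < 3) cfni_stop("need at least 3 carts", "cfni_validation_error")
  fit <- stats::lm(hei_total ~ pct_green + pct_red, data = m)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    cfni_stop("singular design: tier percentages are collinear or constant",
              "cfni_singular_error")
  }
  new_cfni_fit("model3_ols", constant = unname(beta[1]),
               coef_green = unname(beta[2]), coef_red = unname(beta[3]),
               penalty = 0)
}

# Centered/standardized design pieces shared by the ridge paths.
ridge_design <- function(m) {
  X <- cbind(green = m$pct_green, red = m$pct_red)
  y <- m$hei_total
  mx <- colMeans(X)
  sx <- apply(X, 2, stats::sd)
  if (any(sx == 0)) {
    cfni_stop("singular design: a tier percentage is constant",
              "cfni_singular_error")
  }
  Z <- sweep(sweep(X, 2, mx), 2, sx, "/")
  list(Z = Z, y = y, ybar = mean(y), mx = mx, sx = sx, n = nrow(X))
}

ridge_solve <- function(d, lambda) {
  # closed-form ridge on standardized predictors, unpenalized intercept
  yc <- d$y - d$ybar
  A <- crossprod(d$Z) + diag(lambda, ncol(d$Z))
  bz <- drop(solve(A, crossprod(d$Z, yc)))
  braw <- bz / d$sx
  list(coef = braw, constant = d$ybar - sum(braw * d$mx), coef_std = bz)
}

#' Ridge regression fit at a fixed penalty
#'
#' Closed-form ridge solution: predictors are centered and scaled to unit
#' sample SD, the intercept is left unpenalised, and coefficients are reported
#' back on the raw percentage scale. `lambda = 0` reproduces [fit_ols()]
#' exactly.
#'
#' @inheritParams fit_ols
#' @param lambda ridge penalty, `>= 0`, applied on the standardized scale.
#' @return a `cfni_fit`.
#' @export
fit_ridge <- function(summaries, hei, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    cfni_stop("lambda must be a single non-negative number",
              "cfni_validation_error")
  }
  m <- model_frame(summaries, hei)
  d <- ridge_design(m)
  s <- ridge_solve(d, lambda)
  new_cfni_fit("ridge", constant = s$constant,
               coef_green = unname(s$coef["green"]),
               coef_red = unname(s$coef["red"]), penalty = lambda)
}

#' Default penalty grid
#'
#' 101 log-spaced values spanning `[1e-4, 1e4]`.
#' @return numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-4, 4, length.out = 101)

#' Ridge with information-criterion penalty selection (model 1)
#'
#' Evaluates `n * log(RSS/n) + w * df_eff` over the penalty grid, where
#' `df_eff = sum(d_i^2 / (d_i^2 + lambda)) + 1` is the trace of the ridge hat
#' matrix (singular values `d_i` of the standardized design, `+1` for the
#' unpenalised intercept) and `w` is `log(n)` (BIC, default) or 2 (AIC). Ties
#' are broken toward the larger penalty.
#'
#' @inheritParams fit_ols
#' @param lambda_grid candidate penalties (default [default_lambda_grid()]).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return a `cfni_fit` with the selection curve in `$diagnostics`.
#' @export
select_penalty_ic <- function(summaries, hei, lambda_grid = default_lambda_grid(),
                              criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  if (!length(lambda_grid)) cfni_stop("empty penalty grid", "cfni_validation_error")
  lambda_grid <- sort(lambda_grid)
  m <- model_frame(summaries, hei)
  d <- ridge_design(m)
  sv <- svd(d$Z)
  yc <- d$y - d$ybar
  uty <- crossprod(sv$u, yc)
  n <- d$n
  w <- if (criterion == "bic") log(n) else 2
  crit <- df <- rss <- numeric(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    lam <- lambda_grid[i]
    shrink <- sv$d / (sv$d^2 + lam)
    bz <- sv$v %*% (shrink * uty)
    resid <- yc - d$Z %*% bz
    rss[i] <- sum(resid^2)
    df[i] <- sum(sv$d^2 / (sv$d^2 + lam)) + 1
    crit[i] <- n * log(rss[i] / n) + w * df[i]
  }
  crit[is.nan(crit)] <- Inf       # RSS = 0 gives -Inf, a legitimate minimum
  if (all(crit == Inf)) {
    cfni_stop("information criterion non-finite over the whole grid",
              "cfni_selection_error")
  }
  best <- max(which(crit == min(crit)))  # ties -> larger lambda
  s <- ridge_solve(d, lambda_grid[best])
  new_cfni_fit("model1_ridge_ic", constant = s$constant,
               coef_green = unname(s$coef["green"]),
               coef_red = unname(s$coef["red"]),
               penalty = lambda_grid[best],
               diagnostics = list(criterion = criterion, lambda = lambda_grid,
                                  value = crit, df_eff = df, rss = rss))
}

# Equal random partition into k folds: sizes differ by at most one, the
# larger folds first; used by both penalty selection and evaluation CV.
fold_assignment <- function(n, k, seed) {
  sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
  withr::with_seed(seed, {
    idx <- sample.int(n)
    folds <- rep(seq_len(k), sizes)
    out <- integer(n)
    out[idx] <- folds
    out
  })
}

#' Ridge with cross-validated penalty selection (model 2)
#'
#' Mean held-out squared error per penalty over a seeded k-fold split of the
#' carts; the fit at the minimising penalty (ties toward the larger penalty)
#' is refit on all data.
#'
#' @inheritParams select_penalty_ic
#' @param folds number of inner folds (default 10).
#' @param seed integer seed for the fold split.
#' @return a `cfni_fit` with the CV curve in `$diagnostics`.
#' @export
select_penalty_cv <- function(summaries, hei, lambda_grid = default_lambda_grid(),
                              folds = 10, seed = 20220921) {
  if (!length(lambda_grid)) cfni_stop("empty penalty grid", "cfni_validation_error")
  lambda_grid <- sort(lambda_grid)
  m <- model_frame(summaries, hei)
  n <- nrow(m)
  if (folds < 2 || n < folds) {
    cfni_stop("need 2 <= folds <= number of carts", "cfni_validation_error")
  }
  assign <- fold_assignment(n, folds, seed)
  if (min(tabulate(assign, folds)) < 1) {
    cfni_stop("empty cross-validation fold", "cfni_partition_error")
  }
  mse <- matrix(NA_real_, nrow = folds, ncol = length(lambda_grid))
  for (f in seq_len(folds)) {
    train <- m[assign != f, , drop = FALSE]
    test <- m[assign == f, , drop = FALSE]
    d <- ridge_design(train)
    for (i in seq_along(lambda_grid)) {
      s <- ridge_solve(d, lambda_grid[i])
      pred <- s$constant + s$coef["green"] * test$pct_green +
        s$coef["red"] * test$pct_red
      mse[f, i] <- mean((test$hei_total - pred)^2)
    }
  }
  curve <- colMeans(mse)
  best <- max(which(curve == min(curve)))
  d_all <- ridge_design(m)
  s <- ridge_solve(d_all, lambda_grid[best])
  new_cfni_fit("model2_ridge_cv", constant = s$constant,
               coef_green = unname(s$coef["green"]),
               coef_red = unname(s$coef["red"]),
               penalty = lambda_grid[best],
               diagnostics = list(lambda = lambda_grid, cv_mse = curve,
                                  folds = folds, seed = seed))
}

#' Fit the selected weight model
#'
#' Dispatcher over the three model variants.
#'
#' @inheritParams fit_ols
#' @param method `"model1_ridge_ic"`, `"model2_ridge_cv"` or `"model3_ols"`
#'   (aliases `"model1"`, `"model2"`, `"model3"` accepted).
#' @param ... passed to the selected fitter (`criterion`, `lambda_grid`,
#'   `folds`, `seed`).
#' @return a `cfni_fit`.
#' @export
fit_index_model <- function(summaries, hei,
                            method = c("model1_ridge_ic", "model2_ridge_cv",
                                       "model3_ols",
                                       "model1", "model2", "model3"), ...) {
  method <- match.arg(method)
  switch(method,
         model1_ridge_ic = , model1 = select_penalty_ic(summaries, hei, ...),
         model2_ridge_cv = , model2 = select_penalty_cv(summaries, hei, ...),
         model3_ols = , model3 = fit_ols(summaries, hei))
}

#' Predicted HEI under a fitted weight model
#' @param fit a `cfni_fit`.
#' @param summaries tier summaries (`pct_green`, `pct_red`).
#' @return numeric vector of predicted HEI totals.
#' @export
predict_hei <- function(fit, summaries) {
  fit$constant + fit$coef_green * summaries$pct_green +
    fit$coef_red * summaries$pct_red
}

#' Rewrite a fitted model as the three-tier 0-100 index formula
#'
#' For carts `G + Y + R = 100`, the fitted plane
#' `c + bG*G + bR*R` equals `(c/100 + bG)*G + (c/100)*Y + (c/100 + bR)*R`,
#' giving one dimensionless weight per tier. The weighted sum is then
#' anchored to the simplex extremes: `offset = 100 * min(weights)` and
#' `scale = 100 * (max(weights) - min(weights))`, so an all-best-tier cart
#' scores 100 and an all-worst-tier cart scores 0.
#'
#' @param fit a `cfni_fit` (fitted on percentages summing to 100).
#' @return object of class `cfni_formula`: `coef_green_3v`, `coef_yellow_3v`,
#'   `coef_red_3v`, `offset`, `scale`, plus the source method.
#' @export
to_index_formula <- function(fit) {
  wts <- c(green = fit$constant / 100 + fit$coef_green,
           yellow = fit$constant / 100,
           red = fit$constant / 100 + fit$coef_red)
  if (max(wts) == min(wts)) {
    cfni_stop("degenerate formula: all tier weights equal (zero coefficients)",
              "cfni_degenerate_error")
  }
  structure(list(coef_green_3v = unname(wts["green"]),
                 coef_yellow_3v = unname(wts["yellow"]),
                 coef_red_3v = unname(wts["red"]),
                 offset = 100 * min(wts),
                 scale = 100 * (max(wts) - min(wts)),
                 method = fit$method %||% NA_character_),
            class = "cfni_formula")
}

#' @export
print.cfni_formula <- function(x, ...) {
  # constants printed at 4 decimals by convention; arithmetic keeps full precision
  cat(sprintf(
    "CFNI = (((%.4f*Green) + (%.4f*Yellow) + (%.4f*Red)) - %.2f) / %.2f * 100\n",
    x$coef_green_3v, x$coef_yellow_3v, x$coef_red_3v, x$offset, x$scale))
  invisible(x)
}

#' Score carts with an index formula
#'
#' `(wG*G + wY*Y + wR*R - offset) / scale * 100`; guaranteed to lie in
#' `[0, 100]` for compositions on the simplex.
#'
#' @param formula a `cfni_formula`.
#' @param summary tier summaries: a data.frame with `pct_green`, `pct_yellow`,
#'   `pct_red`, or a numeric vector/matrix of `(G, Y, R)` percentages.
#' @return numeric vector of index values.
#' @export
cfni_score <- function(formula, summary) {
  if (is.data.frame(summary)) {
    G <- summary$pct_green; Y <- summary$pct_yellow; R <- summary$pct_red
  } else {
    comp <- rbind(summary)
    if (ncol(comp) != 3) {
      cfni_stop("composition must have three columns (green, yellow, red)",
                "cfni_validation_error")
    }
    G <- comp[, 1]; Y <- comp[, 2]; R <- comp[, 3]
  }
  if (any(abs(G + Y + R - 100) > 1e-6)) {
    cfni_stop("tier percentages must sum to 100 (+/- 1e-6)",
              "cfni_validation_error")
  }
  wsum <- formula$coef_green_3v * G + formula$coef_yellow_3v * Y +
    formula$coef_red_3v * R
  unname((wsum - formula$offset) / formula$scale * 100)
}
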