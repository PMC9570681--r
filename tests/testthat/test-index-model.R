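# tier summaries + HEI laid out for the fitters
fit_frame <- function(comp) {
  list(summaries = comp[c("cart_id", "pct_green", "pct_yellow", "pct_red")],
       hei = comp$hei)
}

noiseless_compositions <- function(n = 60, seed = 5) {
  generate_compositions(composition_params(n_carts = n, noise_sd = 0,
                                           seed = seed))
}

test_that("OLS recovers a noiseless generating plane exactly", {
  comp <- noiseless_compositions()
  f <- fit_frame(comp)
  fit <- fit_ols(f$summaries, f$hei)
  expect_equal(fit$constant, 56.72, tolerance = 1e-8)
  expect_equal(fit$coef_green, 0.270, tolerance = 1e-8)
  expect_equal(fit$coef_red, -0.278, tolerance = 1e-8)
  expect_equal(fit$penalty, 0)
})

test_that("OLS degenerate cases: constant outcome, saturated fit, singular design", {
  comp <- noiseless_compositions(n = 10)
  s <- fit_frame(comp)$summaries
  fit <- fit_ols(s, rep(42, nrow(s)))
  expect_equal(fit$coef_green, 0, tolerance = 1e-10)
  expect_equal(fit$coef_red, 0, tolerance = 1e-10)
  expect_equal(fit$constant, 42, tolerance = 1e-10)
  # 3 non-collinear points interpolate with zero residuals
  s3 <- data.frame(cart_id = c("a", "b", "c"), pct_green = c(10, 50, 80),
                   pct_red = c(70, 20, 10))
  y3 <- c(30, 60, 75)
  fit3 <- fit_ols(s3, y3)
  expect_equal(predict_hei(fit3, s3), y3, tolerance = 1e-9)
  # constant predictor -> singular design
  s_bad <- data.frame(cart_id = c("a", "b", "c", "d"), pct_green = rep(40, 4),
                      pct_red = c(10, 20, 30, 40))
  expect_error(fit_ols(s_bad, c(1, 2, 3, 4)), class = "cfni_singular_error")
})

test_that("ridge closed form matches hand computation and the OLS limit", {
  # single standardized predictor x = (-1, 0, 1), y = (-2, 0, 2):
  # slope = x'y / (x'x + lambda) = 4 / (2 + 2) = 1 at lambda = 2
  d <- list(Z = matrix(c(-1, 0, 1), ncol = 1), y = c(-2, 0, 2), ybar = 0,
            mx = 0, sx = 1, n = 3)
  expect_equal(unname(cfni:::ridge_solve(d, 2)$coef), 1)
  expect_equal(unname(cfni:::ridge_solve(d, 0)$coef), 2)

  comp <- generate_compositions(composition_params(n_carts = 120, seed = 8))
  f <- fit_frame(comp)
  r0 <- fit_ridge(f$summaries, f$hei, 0)
  ols <- fit_ols(f$summaries, f$hei)
  expect_equal(r0$constant, ols$constant, tolerance = 1e-10)
  expect_equal(r0$coef_green, ols$coef_green, tolerance = 1e-10)
  expect_equal(r0$coef_red, ols$coef_red, tolerance = 1e-10)
  # shrinkage limit: coefficients vanish, constant -> mean(y)
  rbig <- fit_ridge(f$summaries, f$hei, 1e12)
  expect_equal(rbig$coef_green, 0, tolerance = 1e-6)
  expect_equal(rbig$coef_red, 0, tolerance = 1e-6)
  expect_equal(rbig$constant, mean(f$hei), tolerance = 1e-4)
  expect_error(fit_ridge(f$summaries, f$hei, -1),
               class = "cfni_validation_error")
})

test_that("ridge coefficient norm is non-increasing in the penalty", {
  comp <- generate_compositions(composition_params(n_carts = 150, seed = 13))
  f <- fit_frame(comp)
  norms <- vapply(default_lambda_grid(), function(lam) {
    fit <- fit_ridge(f$summaries, f$hei, lam)
    sqrt(fit$coef_green^2 + fit$coef_red^2)
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("ridge solution agrees with glmnet under the exact penalty map", {
  skip_if_not_installed("glmnet")
  comp <- generate_compositions(composition_params(n_carts = 200, seed = 21))
  X <- cbind(comp$pct_green, comp$pct_red)
  y <- comp$hei
  Z <- scale(X)   # same standardization as the package: sample SD
  n <- nrow(Z)
  sy <- sqrt(mean((y - mean(y))^2))   # glmnet standardizes y with 1/n SD
  for (lam in c(0.5, 5, 50)) {
    mine <- fit_ridge(fit_frame(comp)$summaries, y, lam)
    bz_mine <- c(mine$coef_green, mine$coef_red) * attr(Z, "scaled:scale")
    g <- glmnet::glmnet(Z, y, alpha = 0, lambda = lam / n * sy,
                        standardize = FALSE, thresh = 1e-14)
    bz_g <- as.numeric(stats::coef(g))[2:3]
    expect_equal(bz_mine, bz_g, tolerance = 1e-6)
  }
})

test_that("information-criterion selection behaves over the grid", {
  comp <- noiseless_compositions(n = 80, seed = 17)
  f <- fit_frame(comp)
  # noiseless data: criterion minimized at the smallest grid penalty
  fit <- select_penalty_ic(f$summaries, f$hei)
  expect_equal(fit$penalty, min(default_lambda_grid()))
  # brute-force check of the stored selection curve at one grid penalty
  lam <- fit$diagnostics$lambda[60]
  Z <- scale(cbind(f$summaries$pct_green, f$summaries$pct_red))
  yc <- f$hei - mean(f$hei)
  bz <- solve(crossprod(Z) + diag(lam, 2), crossprod(Z, yc))
  rss <- sum((yc - Z %*% bz)^2)
  n <- nrow(Z)
  ev <- eigen(crossprod(Z), symmetric = TRUE, only.values = TRUE)$values
  df_expected <- sum(ev / (ev + lam)) + 1
  crit_expected <- n * log(rss / n) + log(n) * df_expected
  i <- which(fit$diagnostics$lambda == lam)
  expect_length(i, 1)
  expect_equal(fit$diagnostics$value[i], crit_expected, tolerance = 1e-8)
  # singleton grid {0} reduces to OLS
  fit0 <- select_penalty_ic(f$summaries, f$hei, lambda_grid = 0)
  ols <- fit_ols(f$summaries, f$hei)
  expect_equal(fit0$coef_green, ols$coef_green, tolerance = 1e-10)
})

test_that("effective degrees of freedom match the eigenvalue formula and decrease", {
  comp <- generate_compositions(composition_params(n_carts = 100, seed = 23))
  f <- fit_frame(comp)
  fit <- select_penalty_ic(f$summaries, f$hei)
  df <- fit$diagnostics$df_eff
  lambda <- fit$diagnostics$lambda
  ev <- eigen(crossprod(scale(cbind(f$summaries$pct_green,
                                    f$summaries$pct_red))),
              symmetric = TRUE, only.values = TRUE)$values
  df_oracle <- vapply(lambda, function(l) sum(ev / (ev + l)) + 1, numeric(1))
  expect_equal(df, df_oracle, tolerance = 1e-9)
  expect_true(all(diff(df) < 0))                    # strictly decreasing
  # at lambda -> 0 the df approach predictors + intercept
  expect_equal(df[1], 3, tolerance = 1e-3)
})

test_that("cross-validated penalty selection is seeded and handles leave-one-out", {
  comp <- generate_compositions(composition_params(n_carts = 60, seed = 31))
  f <- fit_frame(comp)
  grid <- 10^seq(-2, 2, length.out = 9)
  f1 <- select_penalty_cv(f$summaries, f$hei, grid, folds = 10, seed = 77)
  f2 <- select_penalty_cv(f$summaries, f$hei, grid, folds = 10, seed = 77)
  expect_equal(f1$penalty, f2$penalty)
  expect_equal(f1$coef_green, f2$coef_green)
  # noiseless data: held-out error near zero at the small-penalty end
  nl <- noiseless_compositions(n = 40, seed = 32)
  fn <- fit_frame(nl)
  sel <- select_penalty_cv(fn$summaries, fn$hei, grid, folds = 5, seed = 7)
  expect_lte(sel$penalty, grid[2])
  expect_lt(min(sel$diagnostics$cv_mse), 1e-4)
  # leave-one-out runs and returns a finite curve
  loo <- select_penalty_cv(fn$summaries, fn$hei, grid, folds = nrow(nl),
                           seed = 7)
  expect_true(all(is.finite(loo$diagnostics$cv_mse)))
})

test_that("the three-variable transform reproduces the printed formula pattern", {
  # trivial hand arithmetic
  fit <- cfni:::new_cfni_fit("model3_ols", constant = 0, coef_green = 1,
                             coef_red = -1, penalty = 0)
  f <- to_index_formula(fit)
  expect_equal(c(f$coef_green_3v, f$coef_yellow_3v, f$coef_red_3v), c(1, 0, -1))
  expect_equal(f$offset, -100)
  expect_equal(f$scale, 200)
  # degenerate: no slope at all
  flat <- cfni:::new_cfni_fit("model3_ols", 50, 0, 0, 0)
  expect_error(to_index_formula(flat), class = "cfni_degenerate_error")
})

test_that("formula scoring is the affine rescaling of predicted HEI", {
  withr::with_seed(314, {
    for (rep in 1:20) {
      fit <- cfni:::new_cfni_fit("model3_ols", constant = runif(1, 20, 80),
                                 coef_green = runif(1, 0.05, 0.6),
                                 coef_red = -runif(1, 0.05, 0.6), penalty = 0)
      f <- to_index_formula(fit)
      g <- runif(50, 0, 100)
      r <- (100 - g) * runif(50)
      s <- data.frame(pct_green = g, pct_yellow = 100 - g - r, pct_red = r)
      direct <- (predict_hei(fit, s) - f$offset) / f$scale * 100
      expect_equal(cfni_score(f, s), direct, tolerance = 1e-10)
    }
  })
})

test_that("index scores are bounded, monotone across tiers, and linear in mixtures", {
  fit <- cfni:::new_cfni_fit("model3_ols", 56.72, 0.270, -0.278, 0)
  f <- to_index_formula(fit)
  withr::with_seed(271, {
    g <- runif(200, 0, 100)
    r <- (100 - g) * runif(200)
    s <- data.frame(pct_green = g, pct_yellow = 100 - g - r, pct_red = r)
    sc <- cfni_score(f, s)
    expect_true(all(sc >= -1e-9 & sc <= 100 + 1e-9))
    # moving weight red -> yellow and yellow -> green strictly increases
    base <- cfni_score(f, c(40, 30, 30))
    expect_gt(cfni_score(f, c(40, 35, 25)), base)
    expect_gt(cfni_score(f, c(45, 25, 30)), base)
    # linearity: mixture of carts scores the mixture of scores
    a <- c(80, 15, 5); b <- c(10, 30, 60); w <- 0.37
    expect_equal(cfni_score(f, w * a + (1 - w) * b),
                 w * cfni_score(f, a) + (1 - w) * cfni_score(f, b),
                 tolerance = 1e-9)
    # rescaling preserves ranking by predicted HEI
    expect_equal(order(cfni_score(f, s)), order(predict_hei(fit, s)))
  })
  expect_error(cfni_score(f, c(50, 40, 20)), class = "cfni_validation_error")
})

test_that("the model dispatcher reaches all three fitters", {
  comp <- generate_compositions(composition_params(n_carts = 60, seed = 41))
  f <- fit_frame(comp)
  expect_equal(fit_index_model(f$summaries, f$hei, "model3")$method,
               "model3_ols")
  expect_equal(fit_index_model(f$summaries, f$hei, "model1")$method,
               "model1_ridge_ic")
  expect_equal(fit_index_model(f$summaries, f$hei, "model2", folds = 5,
                               seed = 1)$method, "model2_ridge_cv")
})
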