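test_that("response-ordered split reproduces the published counts and keeps extremes", {
  sp <- split_by_response(rnorm(152), stride = 4)
  expect_equal(length(sp$train), 115L)
  expect_equal(length(sp$test), 37L)
  sp <- split_by_response(rnorm(258), stride = 4)
  expect_equal(length(sp$train), 194L)
  expect_equal(length(sp$test), 64L)
  # direct rule application on 9 records in scrambled order
  y <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  sp <- split_by_response(y, stride = 4)
  expect_setequal(y[sp$test], c(4, 8))   # sorted positions 4 and 8
  expect_equal(length(sp$train), 7L)
  expect_error(split_by_response(1:20, stride = 1), "stride")
})

test_that("split always partitions the data and retains global min/max in training", {
  set.seed(5)
  for (n in c(20, 57, 152)) {
    y <- rnorm(n)
    sp <- split_by_response(y, 4)
    expect_setequal(c(sp$train, sp$test), seq_len(n))
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_true(which.min(y) %in% sp$train)
    expect_true(which.max(y) %in% sp$train)
  }
})

test_that("OLS fitting recovers exact and simulated coefficients with diagnostics", {
  # exact linear data: zero residuals, R2 = 1
  X <- matrix(seq_len(20) + 0, 10, 2, dimnames = list(NULL, c("a", "b")))
  X[, 2] <- rnorm(10)
  y <- 2 + 3 * X[, 1] - X[, 2]
  fit <- fit_ols(X, y)
  expect_equal(unname(fit$coefficients), c(2, 3, -1))
  expect_equal(fit$r2, 1)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  # intercept-only fit returns the mean
  f0 <- fit_ols(matrix(numeric(0), 5, 0), c(1, 2, 3, 4, 10))
  expect_equal(unname(f0$coefficients), 4)
  # hat diagonal sums to p' and residuals are orthogonal to the design
  tr <- toy_regression(n = 40, p = 3)
  fit <- fit_ols(tr$X, tr$y)
  expect_equal(sum(fit$hat), 4)
  expect_lt(max(abs(crossprod(fit$X, fit$residuals))), 1e-9)
  expect_true(all(fit$hat >= 1 / 40 - 1e-12))
  # parameter recovery within 3 SE on a larger simulation
  set.seed(88)
  Xl <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  yl <- 0.5 + drop(Xl %*% c(1, -2, 0.5)) + rnorm(200, 0, 0.4)
  fl <- fit_ols(Xl, yl)
  expect_true(all(abs(fl$coefficients - c(0.5, 1, -2, 0.5)) < 3 * fl$se))
  # collinear designs fail naming the columns
  Xc <- cbind(a = rnorm(20), b = 1:20, c = 2 * (1:20))
  expect_error(fit_ols(Xc, rnorm(20)), "collinear")
  # agreement with lm as an independent route
  lmfit <- lm(yl ~ Xl)
  expect_equal(unname(fl$coefficients), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(fl$se), unname(coef(summary(lmfit))[, 2]),
               tolerance = 1e-10)
})

test_that("basic statistics follow their definitions and reproduce table averages", {
  y <- c(1, 2, 3)
  expect_equal(basic_stats(y, y), list(r2 = 1, rmse = 0, mae = 0))
  bs <- basic_stats(c(1, 2), c(0, 3))   # residuals +1, -1
  expect_equal(bs$rmse, 1)
  expect_equal(bs$mae, 1)
  expect_error(basic_stats(c(1, 1), c(1, 2)), "variance")
  # aggregating printed per-fold errors
  expect_equal(mean(c(0.85, 1.06, 0.70, 0.78, 0.58)), 0.794)
  expect_equal(round(mean(c(0.61, 0.78, 0.55, 0.52, 0.48)), 2), 0.59)
  expect_equal(round(mean(c(0.53, 0.73, 0.57, 0.69, 0.72)), 2), 0.65)
})

test_that("hat-identity PRESS equals brute-force leave-one-out refits", {
  for (seed in c(42, 43, 44)) {
    tr <- toy_regression(n = 20, p = 3, seed = seed)
    fit <- fit_ols(tr$X, tr$y)
    press_id <- sum((fit$residuals / (1 - fit$hat))^2)
    press_bf <- sum(vapply(seq_along(tr$y), function(i) {
      f <- fit_ols(tr$X[-i, , drop = FALSE], tr$y[-i])
      (tr$y[i] - predict(f, tr$X[i, , drop = FALSE]))^2
    }, numeric(1)))
    expect_equal(press_id, press_bf, tolerance = 1e-10)
    tss <- sum((tr$y - mean(tr$y))^2)
    expect_equal(q2_loo(tr$X, tr$y), 1 - press_bf / tss, tolerance = 1e-10)
  }
})

test_that("Q2_LOO is 1 for noiseless data and near/below 0 under the null", {
  X <- matrix(rnorm(60), 20, 3); colnames(X) <- letters[1:3]
  y <- 2 - X[, 1] + 0.5 * X[, 3]
  expect_equal(q2_loo(X, y), 1, tolerance = 1e-10)
  set.seed(17)
  Xn <- matrix(rnorm(300), 100, 3); colnames(Xn) <- letters[1:3]
  expect_lt(q2_loo(Xn, rnorm(100)), 0.1)
})

test_that("Q2_LMO is deterministic per seed and close to Q2_LOO at moderate n", {
  set.seed(23)
  X <- matrix(rnorm(200 * 4), 200, 4); colnames(X) <- paste0("d", 1:4)
  y <- 1 + drop(X %*% c(1, -1, 0.5, 0.2)) + rnorm(200, 0, 0.4)
  a <- q2_lmo(X, y, iterations = 300, seed = 9)
  b <- q2_lmo(X, y, iterations = 300, seed = 9)
  expect_identical(a, b)
  expect_lt(abs(a - q2_loo(X, y)), 0.05)
  # noiseless data: exactly 1 for any seed
  y0 <- 1 + drop(X %*% c(1, -1, 0.5, 0.2))
  expect_equal(q2_lmo(X, y0, iterations = 50, seed = 1), 1, tolerance = 1e-9)
})

test_that("Q2-F3 matches hand arithmetic and its limiting behaviours", {
  # hand-computed 3-point example
  y_tr <- c(0, 1, 2); y_ext <- c(0.5, 1.5, 2.5); yhat <- c(0.4, 1.8, 2.2)
  manual <- 1 - (sum((yhat - y_ext)^2) / 3) / (sum((y_tr - 1)^2) / 3)
  expect_equal(q2_f3(y_tr, y_ext, yhat), manual)
  expect_equal(q2_f3(y_tr, y_ext, y_ext), 1)
  # predicting the training mean for external points from the same
  # distribution gives Q2-F3 near zero
  set.seed(12)
  ytr <- rnorm(4000); yext <- rnorm(4000)
  expect_lt(abs(q2_f3(ytr, yext, rep(mean(ytr), 4000))), 0.1)
  expect_error(q2_f3(c(1, 1), y_ext, yhat), "variance")
})

test_that("concordance correlation has its analytic values and Pearson bound", {
  y <- c(1, 2, 3, 5)
  expect_equal(ccc(y, y), 1)
  expect_equal(ccc(y, rep(2, 4)), 0)
  expect_equal(ccc(y - mean(y), -(y - mean(y))), -1)
  # hand-computed with population moments
  yh <- c(1.2, 1.8, 3.4, 4.6)
  my <- mean(y); mh <- mean(yh)
  manual <- 2 * mean((y - my) * (yh - mh)) /
    (mean((y - my)^2) + mean((yh - mh)^2) + (my - mh)^2)
  expect_equal(ccc(y, yh), manual)
  set.seed(3)
  for (r in 1:5) {
    a <- rnorm(30); b <- rnorm(30) + 0.5 * a
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
})

test_that("k-fold CV uses venetian blinds, reduces to LOO at k = n, and recovers signal", {
  set.seed(61)
  X <- as.data.frame(matrix(rnorm(12 * 3), 12, 3)); names(X) <- c("a", "b", "c")
  y <- 1 + X$a - X$b + rnorm(12, 0, 0.2)
  kf <- kfold_cv(y, X, k = 12, ga = NULL)
  press <- sum(kf$per_fold$rmse_test^2)   # each fold holds one point
  fit <- fit_ols(as.matrix(X), y)
  press_id <- sum((fit$residuals / (1 - fit$hat))^2)
  expect_equal(press, press_id, tolerance = 1e-10)
  # per-fold GA selection: informative descriptors dominate the frequencies
  pool <- synthetic_pool(120, 20, seed = 71)
  resp <- generate_response(pool, synthetic_spec(n_molecules = 120, n_true = 3,
                                                 noise_sd = 0.3, seed = 71))
  kf <- kfold_cv(resp$y, pool, k = 5, model_size = 3,
                 ga = ga_config(model_size = 3, population = 30,
                                generations = 25, seed = 5))
  top3 <- names(sort(kf$frequency, decreasing = TRUE))[1:3]
  expect_setequal(top3, resp$truth$names)
  expect_equal(kf$rmse_mean, mean(kf$per_fold$rmse_test))
})

test_that("Q2_LOO does not exceed R2 on fitted models (flagging near-ties)", {
  set.seed(41)
  for (r in 1:5) {
    X <- matrix(rnorm(50 * 4), 50, 4); colnames(X) <- paste0("d", 1:4)
    y <- drop(X %*% rnorm(4)) + rnorm(50, 0, 0.5)
    fit <- fit_ols(X, y)
    q2 <- bmfqsar:::q2_loo_fit(fit)
    if (q2 > fit$r2 + 1e-8)
      warning(sprintf("Q2_LOO %.4f exceeded R2 %.4f", q2, fit$r2))
    expect_lte(q2, fit$r2 + 1e-8)
  }
})
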