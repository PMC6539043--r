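test_that("autoscale standardises, inverts, and carries training params", {
  set.seed(1)
  X <- matrix(rnorm(80, 50, 10), 20, 4)
  sc <- autoscale(X)
  expect_true(all(abs(colMeans(sc$x)) < 1e-12))
  expect_equal(unname(apply(sc$x, 2, sd)), rep(1, 4))
  expect_equal(unscale(sc$x, sc$params), X)

  # validation rows scaled with training params keep non-zero means
  Xv <- matrix(rnorm(40, 70, 10), 10, 4)
  sv <- autoscale(Xv, sc$params)$x
  expect_true(all(abs(colMeans(sv)) > 0.5))

  Xz <- cbind(X, constant = 1)
  expect_error(autoscale(Xz), "constant")
})

test_that("SIMPLS recovers noiseless linear data and matches OLS at full rank", {
  set.seed(2)
  X <- matrix(rnorm(60, 10, 3), 20, 3)
  beta <- c(1.5, -2, 0.5)
  y <- drop(X %*% beta) + 4
  fit <- qsar_pls(list(X = X, y = y), n_lv = 3)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)

  # normal-equations oracle on the 6 x 3 example
  set.seed(3)
  X6 <- matrix(rnorm(18), 6, 3)
  y6 <- rnorm(6)
  sc <- autoscale(X6)
  ys <- (y6 - mean(y6)) / sd(y6)
  b_simpls <- fit_simpls(sc$x, ys, 3)$coefficients
  b_ols <- unname(coef(lm(ys ~ sc$x - 1)))
  expect_equal(unname(b_simpls), b_ols, tolerance = 1e-10)

  # property: equivalence on random full-rank matrices
  for (s in 1:5) {
    set.seed(100 + s)
    n <- sample(8:25, 1); m <- sample(2:5, 1)
    X <- matrix(rnorm(n * m), n, m)
    y <- rnorm(n)
    sc <- autoscale(X)
    ys <- (y - mean(y)) / sd(y)
    expect_equal(unname(fit_simpls(sc$x, ys, m)$coefficients),
                 unname(coef(lm(ys ~ sc$x - 1))), tolerance = 1e-8)
  }
})

test_that("SIMPLS score vectors are orthogonal and rank errors are named", {
  set.seed(4)
  X <- matrix(rnorm(48), 12, 4)
  sc <- autoscale(X)
  f <- fit_simpls(sc$x, drop(scale(rnorm(12))), 4)
  G <- crossprod(f$scores)
  expect_equal(G - diag(diag(G)), matrix(0, 4, 4), ignore_attr = TRUE,
               tolerance = 1e-10)

  X_rank2 <- cbind(X[, 1], X[, 2], X[, 1] + X[, 2])
  Xs <- scale(X_rank2)
  expect_error(fit_simpls(Xs, drop(scale(rnorm(12))), 3), "rank")
})

test_that("pls predictions are invariant to affine rescaling of inputs", {
  set.seed(5)
  X <- matrix(rnorm(100, 20, 5), 25, 4)
  y <- rnorm(25, 1)
  X2 <- sweep(sweep(X, 2, c(2, -1, 10, 0.5), "*"), 2, c(3, 7, -2, 0), "+")
  f1 <- qsar_pls(list(X = X, y = y), n_lv = 2)
  f2 <- qsar_pls(list(X = X2, y = y), n_lv = 2)
  expect_equal(predict(f1, X), predict(f2, X2), tolerance = 1e-10)
})

test_that("rmse matches hand arithmetic", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("LOOCV RMSECV equals an explicit leave-one-out loop", {
  set.seed(6)
  X <- matrix(rnorm(48, 30, 8), 12, 4)
  y <- rnorm(12)
  cv <- loocv_rmsecv(X, y, 1:3)
  # independent loop oracle
  for (a in 1:3) {
    pred <- vapply(1:12, function(i) {
      Xtr <- X[-i, ]; ytr <- y[-i]
      mu <- colMeans(Xtr); sdx <- apply(Xtr, 2, sd)
      muy <- mean(ytr); sdy <- sd(ytr)
      b <- fit_simpls(scale(Xtr, mu, sdx), (ytr - muy) / sdy, a)$coefficients
      muy + sdy * sum((X[i, ] - mu) / sdx * b)
    }, 0)
    expect_equal(cv$rmsecv[a], sqrt(mean((pred - y)^2)), tolerance = 1e-12)
  }
  expect_identical(cv$selected_lv, cv$lv[which.min(cv$rmsecv)])

  # noiseless linear truth: full-rank RMSECV is numerically zero
  yl <- drop(X %*% c(1, -1, 2, 0.5))
  expect_lt(loocv_rmsecv(X, yl, 4)$rmsecv, 1e-8)
})

test_that("cv_anova follows the stated ratio and handles edge cases", {
  r <- cv_anova(c(1, 1, 1, 1), c(2, 2, 2, 2))
  expect_equal(r$F, 4)
  expect_equal(r$p, pf(4, 4, 4, lower.tail = FALSE))

  same <- cv_anova(c(1, -2, 0.5), c(1, -2, 0.5))
  expect_equal(same$F, 1)
  expect_equal(same$p, 0.5, tolerance = 0.01)

  degen <- cv_anova(c(0, 0, 0), c(1, 1, 1))
  expect_true(degen$degenerate)
  expect_identical(degen$p, 0)
})

test_that("jackknife coefficient intervals match an explicit loop", {
  set.seed(7)
  X <- matrix(rnorm(40, 15, 4), 10, 4)
  y <- rnorm(10)
  hw <- coefficient_intervals(X, y, 2, level = 0.95)
  # independent recomputation
  B <- t(sapply(1:10, function(i) {
    Xtr <- X[-i, ]; ytr <- y[-i]
    mu <- colMeans(Xtr); sdx <- apply(Xtr, 2, sd)
    fit_simpls(scale(Xtr, mu, sdx),
               (ytr - mean(ytr)) / sd(ytr), 2)$coefficients
  }))
  se <- sqrt(9 / 10 * colSums(sweep(B, 2, colMeans(B))^2))
  expect_equal(unname(hw), qt(0.975, 9) * se, tolerance = 1e-12)

  # noiseless linear data: the raw-unit coefficients are recovered exactly
  # on every leave-one-out subset (standardised half-widths stay finite
  # because the scaling itself is refit per subset)
  yl <- drop(X %*% c(2, 1, -1, 3))
  for (i in c(1, 5, 10)) {
    f <- qsar_pls(list(X = X[-i, ], y = yl[-i]), n_lv = 4)
    expect_equal(as.numeric(coef(f, raw = TRUE)), c(2, 1, -1, 3),
                 tolerance = 1e-6)
  }
})

test_that("qsar_pls selects by LOOCV and exposes the usual methods", {
  set.seed(8)
  X <- matrix(rnorm(80, 40, 6), 20, 4)
  colnames(X) <- c("ete1", "pa1", "bde1", "he")
  y <- drop(X %*% c(-0.1, -0.2, -0.05, -0.15)) + rnorm(20, 0, 0.1)
  fit <- qsar_pls(list(X = X, y = y))
  expect_s3_class(fit, "qsar_pls")
  expect_identical(fit$n_lv, fit$cv$selected_lv)
  expect_equal(residuals(fit), y - fitted(fit))
  expect_equal(rmse(y, fitted(fit)), fit$rmsee)
  # raw-unit coefficients reproduce predictions
  braw <- coef(fit, raw = TRUE)
  expect_equal(drop(X %*% as.numeric(braw)) + attr(braw, "intercept"),
               predict(fit, X), tolerance = 1e-10)
  # zero-coefficient model predicts the training mean
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(predict(fit0, X), rep(mean(y), 20), ignore_attr = TRUE)
  expect_error(predict(fit, X[, 1:3]), "columns")
})
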