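# Estimator families, prediction contracts, and cross-validation.

test_that("mlr recovers exact linear structure", {
  set.seed(21)
  X <- matrix(runif(40), 20, 2)
  y <- 1.5 - 2 * X[, 1] + 0.7 * X[, 2]
  fit <- ncam_fit(X, y, family = "mlr")
  expect_equal(unname(coef(fit)), c(1.5, -2, 0.7), tolerance = 1e-10)
  expect_equal(predict(fit, X), y, tolerance = 1e-10)
  # constant response: intercept only
  fc <- ncam_fit(X, rep(2, 20), family = "mlr")
  expect_equal(unname(coef(fc)), c(2, 0, 0), tolerance = 1e-10)
  # interaction term captures a pure product
  yi <- X[, 1] * X[, 2]
  fi <- ncam_fit(X, yi, family = "mlr", interaction = TRUE)
  expect_lt(max(abs(residuals(fi))), 1e-10)
  # independent oracle: normal equations
  d <- cbind(1, X, X[, 1] * X[, 2])
  beta <- solve(crossprod(d), crossprod(d, yi))
  expect_equal(unname(coef(fi)), as.numeric(beta), tolerance = 1e-8)
  expect_error(ncam_fit(cbind(X, X[, 1]), y, family = "mlr"), "rank-deficient")
})

test_that("the Matern GP interpolates smooth functions and degenerates gracefully", {
  set.seed(5)
  x <- matrix(seq(0, 3, length.out = 30))
  y <- sin(2 * x[, 1])
  fit <- ncam_fit(x, y, family = "gp_matern")
  expect_lt(max(abs(predict(fit, x) - y)), 0.05)
  xnew <- matrix(seq(0.05, 2.95, length.out = 40))
  expect_lt(sqrt(mean((predict(fit, xnew) - sin(2 * xnew[, 1]))^2)),
            0.01 * diff(range(y)))
  fc <- ncam_fit(x, rep(1.3, 30), family = "gp_matern")
  expect_equal(predict(fc, xnew), rep(1.3, 40), tolerance = 0.02)
})

test_that("quadratic-kernel SVR fits quadratic structure within its tube", {
  set.seed(13)
  X <- matrix(runif(60, -1, 1), 30, 2)
  y <- 0.5 + X[, 1]^2 + 0.3 * X[, 1] * X[, 2] - X[, 2]^2
  fit <- ncam_fit(X, y, family = "svr_quadratic", cost = 1e4, epsilon = 0.001)
  expect_lt(max(abs(predict(fit, X) - y)), 0.001 + 1e-2)
  expect_true(all(is.finite(predict(fit, matrix(runif(10), 5, 2)))))
  fc <- ncam_fit(X, rep(0.7, 30), family = "svr_quadratic")
  expect_equal(predict(fc, X), rep(0.7, 30), tolerance = 1e-6)
})

test_that("NIPALS PLSR matches least squares at full rank and keeps scores orthogonal", {
  set.seed(31)
  X <- matrix(rnorm(60), 20, 3)
  y <- drop(X %*% c(0.5, -1, 2)) + rnorm(20, 0, 0.1)
  fit <- ncam_fit(X, y, family = "plsr", n_lv = 3)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_equal(predict(fit, X), drop(cbind(1, X) %*% ols$coefficients),
               tolerance = 1e-8)
  S <- crossprod(fit$plsr$scores)
  expect_lt(max(abs(S[upper.tri(S)])), 1e-8)
  # one feature, one latent variable: simple linear regression
  x1 <- X[, 1, drop = FALSE]
  f1 <- ncam_fit(x1, y, family = "plsr", n_lv = 1)
  sl <- stats::lm.fit(cbind(1, x1), y)
  expect_equal(predict(f1, x1), drop(cbind(1, x1) %*% sl$coefficients),
               tolerance = 1e-10)
  expect_error(ncam_fit(X, y, family = "plsr", n_lv = 10), "n_lv")
})

test_that("PLSR agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(77)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("b", 1:10)))
  y <- drop(X[, 1] - 0.5 * X[, 4] + rnorm(20, 0, 0.2))
  ours <- ncam_fit(X, y, family = "plsr", n_lv = 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  refp <- predict(ref, X)$predict[, 1, 3]
  expect_equal(unname(predict(ours, X)), unname(refp), tolerance = 1e-6)
})

test_that("prediction contracts: empty input, width mismatch, exact fit", {
  X <- matrix(runif(20), 10, 2)
  y <- 2 + X[, 1] - X[, 2]
  fit <- ncam_fit(X, y, family = "mlr")
  expect_equal(predict(fit, X), y, tolerance = 1e-12)
  expect_length(predict(fit, X[0, , drop = FALSE]), 0)
  expect_error(predict(fit, matrix(1, 2, 3)), "features")
})

test_that("leave-one-out CV equals the closed-form OLS oracle", {
  set.seed(55)
  X <- matrix(runif(60), 30, 2)
  y <- 1 + X[, 1] + 2 * X[, 2] + rnorm(30, 0, 0.05)
  p <- loocv(X, y, family = "mlr")
  expect_length(p, 30)
  # hat-matrix identity: e_loo = e / (1 - h)
  d <- cbind(1, X)
  H <- d %*% solve(crossprod(d), t(d))
  e <- y - drop(H %*% y)
  oracle <- y - e / (1 - diag(H))
  expect_equal(as.numeric(p), oracle, tolerance = 1e-10)
  # noiseless linear data: out-of-fold predictions are exact
  y0 <- 1 + X[, 1] + 2 * X[, 2]
  expect_equal(as.numeric(loocv(X, y0, family = "mlr")), y0, tolerance = 1e-10)
  expect_error(loocv(X[1:2, ], y[1:2]), "at least 3")
})

test_that("loocv refits fold-dependent preprocessing on training rows only", {
  set.seed(91)
  g <- seq(400, 1000, length.out = 50)
  n <- 12
  ndvi <- runif(n, 0.6, 0.74)
  spectra <- t(vapply(ndvi, function(t)
    generate_plant_spectrum(t, wavelength = g)$value, numeric(50)))
  spectra <- spectra * runif(n, 0.8, 1.2)   # multiplicative scatter
  y <- 5 * ndvi + rnorm(n, 0, 0.01)
  p <- loocv(spectra, y, family = "plsr", n_lv = 2,
             preprocess = fit_spectra_preprocessor)
  expect_length(p, n)
  expect_true(all(is.finite(p)))
  expect_gt(stats::cor(as.numeric(p), y), 0.9)
})

test_that("the formula baseline computes the blue-red normalized difference", {
  expect_equal(typical_formula_ndvi(0.5, 0.5), 0)
  expect_equal(typical_formula_ndvi(9, 1), 0.8)
  expect_equal(typical_formula_ndvi(0.6, 0.2), 0.5)
  expect_equal(typical_formula_ndvi(c(1, 3), c(1, 1)), c(0, 0.5))
  expect_error(typical_formula_ndvi(0, 0), "positive")
})
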