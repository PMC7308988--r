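# Regression estimators: multiple linear regression (optionally with an
# interaction), Matern-5/2 Gaussian-process regression, quadratic-kernel
# support-vector regression, NIPALS partial least squares, the two-channel
# formula baseline, and leave-one-out cross-validation.

#' Fit a regression model for camera-based trait estimation
#'
#' One front end over the estimator families used in the analysis chain.
#'
#' * `"mlr"` — ordinary least squares with intercept; `interaction = TRUE`
#'   adds the product of the first two features.
#' * `"gp_matern"` — zero-mean Gaussian process with a Matern-5/2 kernel;
#'   length-scale, signal and noise variances maximize the marginal
#'   likelihood from a fixed multi-start grid (inputs and response are
#'   standardized internally).
#' * `"svr_quadratic"` — epsilon-insensitive support-vector regression with a
#'   degree-2 polynomial kernel (defaults `cost = 1`, `epsilon = 0.001`).
#' * `"plsr"` — NIPALS partial least squares with `n_lv` latent variables
#'   (default 3); successive score vectors are mutually orthogonal.
#'
#' @param x Feature matrix or data.frame (samples x features).
#' @param y Numeric response.
#' @param family One of `"mlr"`, `"gp_matern"`, `"svr_quadratic"`, `"plsr"`.
#' @param interaction Logical (mlr only): add the product of features 1 and 2.
#' @param n_lv Number of latent variables (plsr only).
#' @param cost,epsilon SVR regularization and tube width.
#' @param ... Unused.
#' @return An object of class `"ncam_model"` supporting [predict()],
#'   [coef()], [residuals()], [fitted()], `print()` and `summary()`.
#' @export
ncam_fit <- function(x, y,
                     family = c("mlr", "gp_matern", "svr_quadratic", "plsr"),
                     interaction = FALSE, n_lv = 3,
                     cost = 1, epsilon = 0.001, ...) {
  family <- match.arg(family)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  fit <- switch(family,
    mlr = fit_mlr_(x, y, interaction),
    gp_matern = fit_gp_(x, y),
    svr_quadratic = fit_svr_(x, y, cost, epsilon),
    plsr = fit_plsr_(x, y, n_lv))
  obj <- structure(c(list(family = family, y = y, x = x,
                          p = ncol(x), call = match.call()), fit),
                   class = "ncam_model")
  obj$fitted <- predict(obj, x)
  obj
}

# ---- MLR ------------------------------------------------------------------

mlr_design <- function(x, interaction) {
  d <- cbind(`(Intercept)` = 1, x)
  if (interaction) {
    if (ncol(x) < 2L) stop("interaction needs at least two features")
    d <- cbind(d, `x1:x2` = x[, 1] * x[, 2])
  }
  d
}

fit_mlr_ <- function(x, y, interaction) {
  d <- mlr_design(x, interaction)
  if (nrow(d) <= ncol(d))
    stop("mlr needs more samples than coefficients")
  qr_ <- qr(d)
  if (qr_$rank < ncol(d)) stop("rank-deficient design matrix")
  list(coefficients = qr.coef(qr_, y), interaction = interaction)
}

# ---- Gaussian process, Matern 5/2 -----------------------------------------

matern52 <- function(d) (1 + sqrt(5) * d + 5 * d^2 / 3) * exp(-sqrt(5) * d)

gp_dist <- function(a, b) {
  # Euclidean distances between rows of a and b
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

gp_nll <- function(theta, D, y) {
  ell <- exp(theta[1]); sf2 <- exp(theta[2])^2; sn2 <- exp(theta[3])^2
  K <- sf2 * matern52(D / ell) + diag(sn2 + 1e-10, nrow(D))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  val <- 0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * length(y) * log(2 * pi)
  if (!is.finite(val)) 1e10 else val
}

fit_gp_ <- function(x, y) {
  if (nrow(x) < 3L) stop("gp needs at least 3 samples")
  xc <- colMeans(x); xs <- apply(x, 2, stats::sd); xs[xs == 0] <- 1
  yc <- mean(y); ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  xs_ <- sweep(sweep(x, 2, xc), 2, xs, "/")
  ys_ <- (y - yc) / ys
  D <- gp_dist(xs_, xs_)
  med <- stats::median(D[upper.tri(D)])
  if (!is.finite(med) || med == 0) med <- 1
  starts <- expand.grid(ell = log(med * c(0.3, 1, 3)),
                        sf = log(c(0.5, 1, 2)),
                        sn = log(c(0.05, 0.2)))
  nll <- apply(starts, 1, function(th) gp_nll(as.numeric(th), D, ys_))
  if (all(!is.finite(nll))) stop("gp marginal likelihood non-finite at all starts")
  best <- as.numeric(starts[which.min(nll), ])
  opt <- stats::optim(best, gp_nll, D = D, y = ys_, method = "Nelder-Mead",
                      control = list(maxit = 400))
  th <- opt$par
  ell <- exp(th[1]); sf2 <- exp(th[2])^2; sn2 <- exp(th[3])^2
  K <- sf2 * matern52(D / ell) + diag(sn2 + 1e-10, nrow(D))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys_))
  list(gp = list(xc = xc, xs = xs, yc = yc, ys = ys, xtrain = xs_,
                 ell = ell, sf2 = sf2, sn2 = sn2, alpha = alpha))
}

# ---- SVR, degree-2 polynomial kernel --------------------------------------

fit_svr_ <- function(x, y, cost, epsilon) {
  if (nrow(x) < 3L) stop("svr needs at least 3 samples")
  if (stats::sd(y) == 0) {
    return(list(svr = NULL, const = y[1]))
  }
  m <- e1071::svm(x = x, y = y, type = "eps-regression",
                  kernel = "polynomial", degree = 2,
                  gamma = 1 / ncol(x), coef0 = 1,
                  cost = cost, epsilon = epsilon, scale = TRUE)
  list(svr = m, const = NULL)
}

# ---- PLSR (NIPALS) --------------------------------------------------------

fit_plsr_ <- function(x, y, n_lv) {
  n <- nrow(x); p <- ncol(x)
  if (n_lv < 1L || n_lv > min(n - 1L, p))
    stop("n_lv must be between 1 and min(n - 1, p)")
  xc <- colMeans(x); yc <- mean(y)
  X <- sweep(x, 2, xc); Y <- y - yc
  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  for (k in seq_len(n_lv)) {
    wv <- crossprod(X, Y)
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) stop("degenerate deflation at component ", k)
    wv <- wv / nw
    tv <- X %*% wv
    tt <- sum(tv^2)
    if (tt < 1e-12) stop("degenerate deflation at component ", k)
    pv <- crossprod(X, tv) / tt
    qk <- sum(Y * tv) / tt
    X <- X - tcrossprod(tv, pv)
    Y <- Y - tv * qk
    W[, k] <- wv; P[, k] <- pv; Tm[, k] <- tv; q[k] <- qk
  }
  B <- W %*% solve(crossprod(P, W), q)
  list(plsr = list(xc = xc, yc = yc, coef = drop(B), n_lv = n_lv,
                   scores = Tm, loadings = P, weights = W, q = q))
}

# ---- methods ---------------------------------------------------------------

#' Predict from a fitted model
#'
#' @param object An `"ncam_model"`.
#' @param newdata Feature matrix with the same number of columns as at fit
#'   time; zero rows give an empty prediction.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.ncam_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric(0))
  if (ncol(newdata) != object$p)
    stop("newdata has ", ncol(newdata), " features; model expects ", object$p)
  storage.mode(newdata) <- "double"
  out <- switch(object$family,
    mlr = drop(mlr_design(newdata, object$interaction) %*% object$coefficients),
    gp_matern = {
      g <- object$gp
      xs_ <- sweep(sweep(newdata, 2, g$xc), 2, g$xs, "/")
      Ks <- g$sf2 * matern52(gp_dist(xs_, g$xtrain) / g$ell)
      drop(Ks %*% g$alpha) * g$ys + g$yc
    },
    svr_quadratic = {
      if (is.null(object$svr)) rep(object$const, nrow(newdata))
      else as.numeric(stats::predict(object$svr, newdata))
    },
    plsr = {
      pl <- object$plsr
      drop(sweep(newdata, 2, pl$xc) %*% pl$coef) + pl$yc
    })
  if (any(!is.finite(out))) stop("non-finite predictions")
  out
}

#' @export
coef.ncam_model <- function(object, ...) {
  switch(object$family,
    mlr = object$coefficients,
    plsr = c(`(Intercept)` = object$plsr$yc -
               sum(object$plsr$xc * object$plsr$coef), object$plsr$coef),
    stop("coefficients are only defined for mlr and plsr fits"))
}

#' @export
fitted.ncam_model <- function(object, ...) object$fitted

#' @export
residuals.ncam_model <- function(object, ...) object$y - object$fitted

#' @export
print.ncam_model <- function(x, ...) {
  cat(sprintf("<ncam_model: %s> n = %d, features = %d\n",
              x$family, length(x$y), x$p))
  if (x$family %in% c("mlr", "plsr")) {
    cat("coefficients:\n"); print(round(coef(x), 6))
  }
  invisible(x)
}

#' @export
summary.ncam_model <- function(object, ...) {
  r <- residuals(object)
  cat(sprintf("family: %s, n = %d, features = %d\n",
              object$family, length(object$y), object$p))
  cat(sprintf("training RMSE = %.4g, R2 = %.4f\n",
              sqrt(mean(r^2)),
              1 - sum(r^2) / sum((object$y - mean(object$y))^2)))
  invisible(object)
}

#' Leave-one-out cross-validation
#'
#' Each sample is predicted by a model fit to all other samples; any
#' fold-dependent preprocessing is refit per fold through `preprocess`.
#'
#' @param x Feature (or raw spectra) matrix.
#' @param y Numeric response.
#' @param family,... Passed to [ncam_fit()].
#' @param preprocess Optional `function(x_train)` returning a list with
#'   `values` (preprocessed training matrix) and `transform(x_new)`; e.g.
#'   [fit_spectra_preprocessor()].
#' @return Numeric vector of `length(y)` out-of-fold predictions, in input
#'   order, with attributes `family` and `y`.
#' @export
loocv <- function(x, y, family = "mlr", preprocess = NULL, ...) {
  x <- as.matrix(x)
  n <- length(y)
  if (n < 3L) stop("loocv needs at least 3 samples")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]; yt <- y[-i]
    xv <- x[i, , drop = FALSE]
    if (!is.null(preprocess)) {
      pp <- preprocess(xt)
      xt <- pp$values
      xv <- pp$transform(xv)
    }
    fit <- tryCatch(ncam_fit(xt, yt, family = family, ...),
                    error = function(e) stop("loocv fold ", i, ": ",
                                             conditionMessage(e)))
    preds[i] <- predict(fit, xv)
  }
  structure(preds, family = family, y = y)
}

#' Two-channel formula NDVI baseline
#'
#' `(Bc - Rc) / (Bc + Rc)` from the averaged blue and red channel values of a
#' camera image — the conventional estimator the learned models are compared
#' against.
#'
#' @param Bc,Rc Averaged blue and red channel values (vectorized).
#' @return NDVI estimate(s).
#' @export
typical_formula_ndvi <- function(Bc, Rc) {
  den <- Bc + Rc
  if (any(den <= 0)) stop("Bc + Rc must be positive")
  (Bc - Rc) / den
}
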