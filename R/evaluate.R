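# Evaluation: R2, RMSE, MAE, MPE, Bland-Altman agreement, and the
# estimator comparison table.

#' Regression performance metrics
#'
#' `R2 = 1 - SSres/SStot`, root-mean-square error, mean absolute error, and
#' mean percentage error. MPE is the MAE divided by the mean ground-truth
#' value, in percent (`mpe = "aggregate"`, the default); `"per_sample"`
#' averages the per-sample absolute percentage errors instead.
#'
#' @param y_true Ground-truth values.
#' @param y_pred Predictions, same length.
#' @param label Optional estimator label.
#' @param mpe `"aggregate"` or `"per_sample"`.
#' @return Object of class `"metrics_report"`: list with `r2`, `rmse`, `mae`,
#'   `mpe` (percent), `n`, `label`.
#' @export
regression_metrics <- function(y_true, y_pred, label = NULL,
                               mpe = c("aggregate", "per_sample")) {
  mpe <- match.arg(mpe)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  n <- length(y_true)
  if (n < 2L) stop("metrics need at least 2 samples")
  sstot <- sum((y_true - mean(y_true))^2)
  if (sstot == 0) stop("R2 undefined: ground truth has zero variance")
  err <- y_true - y_pred
  mae <- mean(abs(err))
  mpe_val <- if (mpe == "aggregate") {
    if (mean(y_true) == 0) stop("MPE undefined: mean ground truth is zero")
    100 * mae / mean(y_true)
  } else {
    if (any(y_true == 0)) stop("per-sample MPE undefined at zero ground truth")
    100 * mean(abs(err / y_true))
  }
  structure(list(r2 = 1 - sum(err^2) / sstot,
                 rmse = sqrt(mean(err^2)), mae = mae, mpe = mpe_val,
                 n = n, label = label %||% "estimator"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s (n = %d): R2 = %.4f, RMSE = %.4g, MAE = %.4g, MPE = %.2f%%\n",
              x$label, x$n, x$r2, x$rmse, x$mae, x$mpe))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `m1 - m2`, their mean (bias), the 95% limits of agreement
#' `bias +/- 1.96 * sd` (sample standard deviation), and the fraction of
#' differences falling within the limits.
#'
#' @param m1,m2 Paired measurements, length >= 2.
#' @return Object of class `"bland_altman"`: list with `differences`,
#'   `means`, `bias`, `loa_lower`, `loa_upper`, `frac_within`, `n`.
#' @export
bland_altman <- function(m1, m2) {
  if (length(m1) != length(m2)) stop("length mismatch")
  n <- length(m1)
  if (n < 2L) stop("Bland-Altman needs at least 2 pairs")
  d <- m1 - m2
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - 1.96 * s; hi <- bias + 1.96 * s
  structure(list(differences = d, means = (m1 + m2) / 2, bias = bias,
                 loa_lower = lo, loa_upper = hi,
                 frac_within = mean(d >= lo & d <= hi), n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias = %.4g, limits [%.4g, %.4g], %.1f%% within\n",
              x$n, x$bias, x$loa_lower, x$loa_upper, 100 * x$frac_within))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ..., xlab = "mean of methods",
                              ylab = "difference") {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Compare estimators evaluated on the same samples
#'
#' @param reports List of `"metrics_report"`s over the same sample set.
#' @return Object of class `"method_comparison"`: list with `table`
#'   (one row per estimator), `delta_r2` (pairwise R2 differences,
#'   row minus column) and `best` (label with the highest R2).
#' @export
compare_methods <- function(reports) {
  if (length(reports) < 2L) stop("need at least two reports to compare")
  ns <- vapply(reports, function(r) r$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("reports cover different sample counts: ", paste(ns, collapse = ", "))
  labels <- vapply(reports, function(r) r$label, character(1))
  tab <- data.frame(
    estimator = labels,
    r2 = vapply(reports, function(r) r$r2, numeric(1)),
    rmse = vapply(reports, function(r) r$rmse, numeric(1)),
    mae = vapply(reports, function(r) r$mae, numeric(1)),
    mpe = vapply(reports, function(r) r$mpe, numeric(1)),
    n = ns, stringsAsFactors = FALSE)
  d <- outer(tab$r2, tab$r2, "-")
  dimnames(d) <- list(labels, labels)
  structure(list(table = tab, delta_r2 = d,
                 best = labels[which.max(tab$r2)]),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  print(transform(x$table, r2 = round(r2, 4), rmse = signif(rmse, 4),
                  mae = signif(mae, 4), mpe = round(mpe, 2)))
  cat("best estimator:", x$best, "\n")
  invisible(x)
}
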