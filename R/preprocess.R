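# Feature conditioning: channel-sum normalization for camera features;
# absorbance transform, multiplicative scatter correction and mean centering
# for spectra.

#' Channel-sum normalization of camera features
#'
#' Scales each channel by the sum of its plant's three channel values,
#' removing per-plant brightness. Returns the red and blue ratios only; the
#' green ratio is implied (`1 - r - b`) and is omitted to avoid redundancy.
#'
#' @param triplet Numeric vector `c(R, G, B)` or an `n x 3` matrix/data.frame.
#' @return A data.frame with columns `r` and `b` in `[0, 1]`, `r + b <= 1`.
#' @export
channel_sum_normalize <- function(triplet) {
  m <- if (is.null(dim(triplet))) matrix(triplet, nrow = 1) else as.matrix(triplet)
  if (ncol(m) != 3L) stop("expected three channel values per plant")
  s <- rowSums(m)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("channel sums must be positive")
  data.frame(r = m[, 1] / s, b = m[, 3] / s)
}

#' Absorbance-style log transform of reflectance spectra
#'
#' `log10(1/x)` (the chemometrics absorbance convention) by default;
#' `kind = "log"` gives the natural log of reflectance instead.
#'
#' @param x Numeric matrix (samples x bands) or vector; all values `> 0`.
#' @param kind `"absorbance"` (default) or `"log"`.
#' @return Transformed matrix/vector.
#' @export
log_transform <- function(x, kind = c("absorbance", "log")) {
  kind <- match.arg(kind)
  bad <- which(!(x > 0))
  if (length(bad))
    stop("log transform needs positive values; offending cells: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (kind == "absorbance") -log10(x) else log(x)
}

#' Multiplicative scatter correction
#'
#' Regresses each sample spectrum on a reference spectrum over bands
#' (`x ~ a + b * ref`, ordinary least squares) and returns `(x - a) / b`,
#' removing per-sample additive offset and multiplicative scatter. The
#' reference defaults to the column mean of `x`; pass the stored training
#' reference to correct held-out samples without leakage.
#'
#' @param x Numeric matrix, samples in rows.
#' @param reference Optional reference spectrum (length `ncol(x)`).
#' @return List with `values` (corrected matrix) and `reference`.
#' @export
msc <- function(x, reference = NULL) {
  x <- as.matrix(x)
  if (is.null(reference)) {
    if (nrow(x) < 2L) stop("msc needs >= 2 samples when no reference is given")
    reference <- colMeans(x)
  }
  if (length(reference) != ncol(x)) stop("reference length must equal band count")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom <= 0) stop("msc reference has no variation across bands")
  out <- x
  for (i in seq_len(nrow(x))) {
    b <- sum((x[i, ] - mean(x[i, ])) * rc) / denom
    if (abs(b) < 1e-10)
      stop("msc slope ~ 0 for sample ", rownames(x)[i] %||% i)
    a <- mean(x[i, ]) - b * mean(reference)
    out[i, ] <- (x[i, ] - a) / b
  }
  list(values = out, reference = reference)
}

#' Mean centering
#'
#' Subtracts column means; adding the returned `center` back reconstructs the
#' input exactly.
#'
#' @param x Numeric matrix (samples x bands).
#' @param center Optional precomputed column means (for held-out samples).
#' @return List with `values` and `center`.
#' @export
mean_center <- function(x, center = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  list(values = sweep(x, 2, center, "-"), center = center)
}

#' Fit the spectral preprocessing chain on training spectra
#'
#' Absorbance transform, multiplicative scatter correction against the
#' training mean, then mean centering with the training column means. The
#' returned object applies the identical, training-derived transform to new
#' samples, so cross-validation folds see no information from held-out rows.
#'
#' @param x Training spectra matrix (samples x bands), reflectance factors.
#' @param kind Log transform variant, see [log_transform()].
#' @return List with `values` (preprocessed training matrix), `reference`,
#'   `center` and `transform` (a function of a new spectra matrix).
#' @export
fit_spectra_preprocessor <- function(x, kind = "absorbance") {
  a <- log_transform(as.matrix(x), kind)
  m <- msc(a)
  cen <- mean_center(m$values)
  transform <- function(xnew) {
    xnew <- as.matrix(xnew)
    an <- log_transform(xnew, kind)
    mn <- msc(an, reference = m$reference)
    mean_center(mn$values, center = cen$center)$values
  }
  list(values = cen$values, reference = m$reference, center = cen$center,
       transform = transform)
}
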