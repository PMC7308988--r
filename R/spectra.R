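# Wavelength grids, reflectance spectra, hyperspectral cubes, and the
# NDVI ground-truth band algebra.

#' Default hyperspectral wavelength grid
#'
#' 400--1000 nm sampled at 513 points, the processed-product resolution of
#' the reference hyperspectral camera (about 1.17 nm spacing).
#'
#' @return Numeric vector of wavelengths in nanometres.
#' @export
default_grid <- function() seq(400, 1000, length.out = 513)

#' Construct a wavelength grid
#'
#' @param wavelengths_nm Strictly increasing numeric vector (nm), length >= 2.
#' @return The validated numeric vector, classed `"wavelength_grid"`.
#' @export
wavelength_grid <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 2L) stop("a wavelength grid needs at least 2 points")
  if (any(!is.finite(w))) stop("wavelengths must be finite")
  if (any(diff(w) <= 0)) stop("wavelengths must be strictly increasing")
  structure(w, class = "wavelength_grid")
}

#' Construct a reflectance spectrum
#'
#' A reflectance-factor spectrum sampled on a wavelength grid. Values are
#' dimensionless and nonnegative.
#'
#' @param wavelength Wavelengths in nm (or a [wavelength_grid()]).
#' @param value Reflectance factor at each wavelength, `>= 0`.
#' @return An object of class `"spectrum"` with fields `wavelength`, `value`.
#' @export
spectrum <- function(wavelength, value) {
  w <- wavelength_grid(wavelength)
  v <- as.numeric(value)
  if (length(v) != length(w)) stop("value length must match grid length")
  if (any(!is.finite(v))) stop("spectrum values must be finite")
  if (any(v < 0)) stop("reflectance factors must be nonnegative")
  structure(list(wavelength = as.numeric(w), value = v), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bands, %.1f-%.1f nm, range [%.4g, %.4g]\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$value), max(x$value)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ..., xlab = "wavelength (nm)",
                          ylab = "reflectance factor", type = "l") {
  graphics::plot(x$wavelength, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Construct a hyperspectral cube
#'
#' @param values Numeric array `height x width x bands`, nonnegative.
#' @param wavelength Wavelengths (nm), one per band.
#' @return Object of class `"hscube"`: the array with a `wavelength` attribute.
#' @export
hscube <- function(values, wavelength) {
  w <- as.numeric(wavelength_grid(wavelength))
  if (length(dim(values)) != 3L) stop("cube must be a 3-d array (row, col, band)")
  if (dim(values)[3L] != length(w)) stop("band axis must match grid length")
  if (any(values < 0)) stop("cube values must be nonnegative")
  structure(values, wavelength = w, class = "hscube")
}

#' @export
print.hscube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<hscube> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(attr(x, "wavelength")),
              max(attr(x, "wavelength"))))
  invisible(x)
}

#' Cube pixel spectra as a matrix
#'
#' Flattens a cube to a `(pixels x bands)` matrix in column-major pixel order.
#' @param cube An [hscube()].
#' @return Numeric matrix.
#' @export
cube_matrix <- function(cube) {
  d <- dim(cube)
  matrix(cube, nrow = d[1] * d[2], ncol = d[3])
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation; exact at shared grid points. Extrapolation outside
#' the source span is refused.
#'
#' @param spec A [spectrum()].
#' @param target Target wavelengths (nm).
#' @return A [spectrum()] on the target grid.
#' @export
resample_spectrum <- function(spec, target) {
  tw <- as.numeric(wavelength_grid(target))
  if (min(tw) < min(spec$wavelength) || max(tw) > max(spec$wavelength))
    stop("target grid extends outside the source span; refusing to extrapolate")
  v <- stats::approx(spec$wavelength, spec$value, xout = tw, method = "linear")$y
  spectrum(tw, v)
}

#' Mean band intensity over a closed wavelength window
#'
#' Averages the spectrum values at grid points falling in
#' `[center - half_width, center + half_width]`. A zero half-width returns the
#' value at the nearest grid point.
#'
#' @param spec A [spectrum()].
#' @param center_nm Window centre (nm).
#' @param half_width_nm Window half width (nm), `>= 0`.
#' @return Scalar mean intensity.
#' @export
band_intensity <- function(spec, center_nm, half_width_nm = 5) {
  if (half_width_nm < 0) stop("half_width_nm must be >= 0")
  if (half_width_nm == 0)
    return(spec$value[which.min(abs(spec$wavelength - center_nm))])
  keep <- spec$wavelength >= center_nm - half_width_nm &
    spec$wavelength <= center_nm + half_width_nm
  if (!any(keep)) stop("band window contains no grid points")
  mean(spec$value[keep])
}

#' NDVI from a reflectance spectrum
#'
#' The hyperspectral ground-truth definition: `(b850 - b680) / (b850 + b680)`
#' with `b850`, `b680` the mean intensities in 5 nm half-width windows around
#' 850 and 680 nm (about 9 grid points each on the default 513-band grid).
#'
#' @param spec A [spectrum()].
#' @param half_width_nm Band half width (nm); default 5.
#' @return NDVI in `[-1, 1]`.
#' @export
ndvi_from_spectrum <- function(spec, half_width_nm = 5) {
  b850 <- band_intensity(spec, 850, half_width_nm)
  b680 <- band_intensity(spec, 680, half_width_nm)
  if (b850 + b680 <= 0) stop("NDVI undefined: b850 + b680 must be positive")
  (b850 - b680) / (b850 + b680)
}

#' Skewness of a sample
#'
#' `sum((x - mu)^3) / (n * s^3)`. By default `s` is the population standard
#' deviation (divide by `n`), so numerator and denominator share the same `n`;
#' set `type = "sample"` for the `n - 1` denominator.
#'
#' @param values Numeric vector, length >= 2, nonzero spread.
#' @param type `"population"` (default) or `"sample"` standard deviation.
#' @return Scalar skewness.
#' @export
skewness <- function(values, type = c("population", "sample")) {
  type <- match.arg(type)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2L) stop("skewness needs at least 2 values")
  mu <- mean(x)
  s2 <- if (type == "population") mean((x - mu)^2) else stats::var(x)
  if (s2 <= 0) stop("skewness undefined for a zero-variance sample")
  sum((x - mu)^3) / (n * s2^1.5)
}

#' Descriptive statistics of a cohort variable
#'
#' Mean, minimum, maximum, variance, coefficient of variation
#' (standard deviation / mean) and skewness. Variance and CV use the sample
#' (`n - 1`) convention; skewness uses [skewness()] with its population
#' default.
#'
#' @param values Numeric vector, length >= 2.
#' @return A list of class `"cohort_summary"` with fields `mean`, `minimum`,
#'   `maximum`, `variance`, `coefficient_of_variation`, `skewness`, `n`.
#' @export
cohort_summary <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 2L) stop("cohort_summary needs at least 2 values")
  m <- mean(x)
  v <- stats::var(x)
  if (m == 0) stop("coefficient of variation undefined: mean is zero")
  structure(list(
    mean = m, minimum = min(x), maximum = max(x), variance = v,
    coefficient_of_variation = sqrt(v) / m,
    skewness = if (v > 0) skewness(x) else 0,
    n = length(x)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d  mean = %.4g  min = %.4g  max = %.4g\nvar = %.4g  CV = %.4g  skewness = %.4g\n",
    x$n, x$mean, x$minimum, x$maximum, x$variance,
    x$coefficient_of_variation, x$skewness))
  invisible(x)
}
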