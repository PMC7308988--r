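# Forward model of the NIR-sensitive RGB camera: channel sensitivity curves,
# optical filters, channel responses, band-sensitivity matrices, and the
# channel-purity algebra.

#' Construct a channel sensitivity set
#'
#' Three nonnegative relative-response curves (R, G, B) on a shared
#' wavelength grid.
#'
#' @param wavelength Wavelengths (nm).
#' @param sens Numeric matrix `length(wavelength) x 3`, columns R, G, B.
#' @return Object of class `"sensitivity_set"`.
#' @export
sensitivity_set <- function(wavelength, sens) {
  w <- as.numeric(wavelength_grid(wavelength))
  sens <- as.matrix(sens)
  if (nrow(sens) != length(w) || ncol(sens) != 3L)
    stop("sens must be a length(wavelength) x 3 matrix (R, G, B)")
  if (any(sens < 0)) stop("sensitivities must be nonnegative")
  colnames(sens) <- c("R", "G", "B")
  structure(list(wavelength = w, sens = sens), class = "sensitivity_set")
}

#' @export
print.sensitivity_set <- function(x, ...) {
  cat(sprintf("<sensitivity_set> %d points, %.0f-%.0f nm, peak responses R=%.2f G=%.2f B=%.2f\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              max(x$sens[, 1]), max(x$sens[, 2]), max(x$sens[, 3])))
  invisible(x)
}

#' Parameterized NIR-sensitive RGB sensor sensitivities
#'
#' A Gaussian-mixture stand-in for a de-filtered consumer CMOS sensor
#' (synthetic; no measured curves are shipped). Each channel has a visible
#' Gaussian peak (R near 600 nm, G near 540 nm, B near 460 nm), a small
#' common visible cross-talk floor, and a shared NIR shoulder rising past
#' 700 nm, so beyond about 800 nm the three channels respond approximately
#' equally.
#'
#' @param wavelength Wavelengths (nm); default [default_grid()].
#' @param nir_amplitude Relative NIR shoulder height (default 0.30).
#' @param crosstalk Visible cross-talk floor (default 0.01).
#' @return A [sensitivity_set()].
#' @export
rgbn_sensitivities <- function(wavelength = default_grid(),
                               nir_amplitude = 0.30, crosstalk = 0.01) {
  w <- as.numeric(wavelength_grid(wavelength))
  gauss <- function(mu, sd, amp) amp * exp(-((w - mu)^2) / (2 * sd^2))
  nir <- nir_amplitude * stats::plogis((w - 705) / 8) *
    exp(-((w - 820)^2) / (2 * 180^2))
  floorv <- crosstalk * stats::plogis((700 - w) / 15)
  sens <- cbind(
    R = gauss(600, 55, 0.92) + floorv + nir,
    G = gauss(540, 45, 0.88) + floorv + nir,
    B = gauss(460, 40, 0.95) + floorv + nir
  )
  sensitivity_set(w, sens)
}

#' Typical (NIR-rejected) RGB camera sensitivities
#'
#' The same visible Gaussian channels without the NIR shoulder; used for
#' true-color rendering of hyperspectral cubes.
#'
#' @inheritParams rgbn_sensitivities
#' @return A [sensitivity_set()] with no response above about 720 nm.
#' @export
typical_rgb_sensitivities <- function(wavelength = default_grid(),
                                      crosstalk = 0.01) {
  rgbn_sensitivities(wavelength, nir_amplitude = 0, crosstalk = crosstalk)
}

#' Optical filter specification
#'
#' @param kind `"long_pass"` or `"two_band_pass"`.
#' @param cutoff_nm Long-pass cut-on wavelength (default 580 nm).
#' @param transition_nm Long-pass 12--88% transition width (default 10 nm).
#' @param centers_nm Two-band-pass centres (default `c(650, 850)` nm).
#' @param fwhm_nm Full width at half maximum of each passband (default 40 nm).
#' @return Object of class `"filter_spec"`.
#' @export
filter_spec <- function(kind = c("long_pass", "two_band_pass"),
                        cutoff_nm = 580, transition_nm = 10,
                        centers_nm = c(650, 850), fwhm_nm = 40) {
  kind <- match.arg(kind)
  if (kind == "long_pass" && (cutoff_nm <= 0 || transition_nm <= 0))
    stop("long-pass cutoff and transition width must be positive")
  if (kind == "two_band_pass" && (length(centers_nm) < 1L || any(fwhm_nm <= 0)))
    stop("two-band-pass needs at least one centre and positive FWHM")
  structure(list(kind = kind, cutoff_nm = cutoff_nm,
                 transition_nm = transition_nm, centers_nm = centers_nm,
                 fwhm_nm = fwhm_nm), class = "filter_spec")
}

#' Filter transmission curve on a grid
#'
#' Long-pass: logistic step rising at the cutoff (12--88% over
#' `transition_nm`). Two-band-pass: sum of Gaussian passbands with the stated
#' centres and FWHM (so transmission is exactly half the peak at
#' `centre +/- FWHM/2`), clipped to `[0, 1]`.
#'
#' @param spec A [filter_spec()].
#' @param wavelength Wavelengths (nm).
#' @return Numeric transmission vector in `[0, 1]`.
#' @export
make_filter <- function(spec, wavelength = default_grid()) {
  w <- as.numeric(wavelength_grid(wavelength))
  if (spec$kind == "long_pass") {
    tr <- stats::plogis((w - spec$cutoff_nm) / (spec$transition_nm / 4))
  } else {
    if (any(spec$centers_nm < min(w)) || any(spec$centers_nm > max(w)))
      stop("passband centre outside the wavelength grid span")
    sd <- spec$fwhm_nm / (2 * sqrt(2 * log(2)))
    tr <- rowSums(vapply(seq_along(spec$centers_nm), function(i)
      exp(-((w - spec$centers_nm[i])^2) / (2 * sd[min(i, length(sd))]^2)),
      numeric(length(w))))
  }
  pmin(pmax(tr, 0), 1)
}

#' Apply a filter to a sensitivity set
#'
#' Pointwise product of each channel curve with the transmission curve.
#'
#' @param sens A [sensitivity_set()].
#' @param transmission Numeric transmission vector on the same grid, or a
#'   [filter_spec()] (evaluated on the set's grid).
#' @return A filtered [sensitivity_set()].
#' @export
apply_filter <- function(sens, transmission) {
  if (inherits(transmission, "filter_spec"))
    transmission <- make_filter(transmission, sens$wavelength)
  if (length(transmission) != length(sens$wavelength))
    stop("transmission grid does not match the sensitivity grid")
  sensitivity_set(sens$wavelength, sens$sens * transmission)
}

#' Simulate RGB channel responses to a reflectance spectrum
#'
#' Each channel value is the trapezoidal integral over wavelength of
#' reflectance x illumination x channel sensitivity; linear in the spectrum.
#'
#' @param spec A [spectrum()] (plant reflectance factor).
#' @param eff_sens Effective (filtered) [sensitivity_set()] on the same grid.
#' @param illumination Optional [spectrum()] on the same grid; default flat 1.
#' @return Named numeric vector `c(R, G, B)`, nonnegative.
#' @export
simulate_channels <- function(spec, eff_sens, illumination = NULL) {
  if (length(spec$wavelength) != length(eff_sens$wavelength) ||
      any(abs(spec$wavelength - eff_sens$wavelength) > 1e-9))
    stop("spectrum and sensitivity grids do not match")
  ill <- if (is.null(illumination)) rep(1, length(spec$wavelength)) else {
    if (length(illumination$value) != length(spec$wavelength))
      stop("illumination grid does not match")
    illumination$value
  }
  w <- trapz_weights(spec$wavelength)
  drop((spec$value * ill * w) %*% eff_sens$sens)
}

#' Half-open spectral band window
#'
#' @param lo_nm,hi_nm Window bounds (nm), `lo_nm < hi_nm`; interpreted as
#'   `[lo, hi)`. Windows extending past the grid are truncated at its maximum.
#' @return Object of class `"band_window"`.
#' @export
band_window <- function(lo_nm, hi_nm) {
  if (lo_nm >= hi_nm) stop("band window needs lo < hi")
  structure(list(lo_nm = lo_nm, hi_nm = hi_nm), class = "band_window")
}

#' Canonical red/NIR windows for the two camera systems
#'
#' Long-pass system: red 580--700 nm, NIR 700--1100 nm (truncated at the grid
#' maximum). Two-band-pass system: red 620--690 nm, NIR 810--890 nm.
#'
#' @param system `"lp"` or `"tp"`.
#' @return List of two [band_window()]s, `red` and `nir`.
#' @export
system_windows <- function(system = c("lp", "tp")) {
  system <- match.arg(system)
  if (system == "lp")
    list(red = band_window(580, 700), nir = band_window(700, 1100))
  else
    list(red = band_window(620, 690), nir = band_window(810, 890))
}

#' Band-sensitivity matrix of an effective sensitivity set
#'
#' Entry `(channel, band)` is the mean effective sensitivity over the grid
#' points in the half-open band window, so a flat unit sensitivity maps to 1.
#'
#' @param eff_sens A [sensitivity_set()].
#' @param windows List of [band_window()]s.
#' @return `3 x length(windows)` matrix (rows R, G, B).
#' @export
band_sensitivity_matrix <- function(eff_sens, windows) {
  w <- eff_sens$wavelength
  out <- vapply(windows, function(win) {
    keep <- w >= win$lo_nm & w < win$hi_nm
    if (!any(keep)) stop("band window contains no grid points")
    colMeans(eff_sens$sens[keep, , drop = FALSE])
  }, numeric(3))
  out <- matrix(out, nrow = 3,
                dimnames = list(c("R", "G", "B"),
                                names(windows) %||% seq_along(windows)))
  out
}

#' Calibrated channel value under the two-band purity model
#'
#' For a channel sensing only red and NIR light, the whiteboard-calibrated
#' value is `(alpha*lambda*Nw + beta*theta*Rw) / (alpha*Nw + beta*Rw)`, where
#' `alpha`, `beta` are the channel's NIR and red sensitivities, `lambda`,
#' `theta` the plant-to-whiteboard reflectance ratios in NIR and red, and
#' `Nw`, `Rw` the whiteboard NIR and red reflectance. As the NIR-red
#' sensitivity ratio `alpha/beta` grows the value tends to `lambda` (pure
#' NIR); as it shrinks it tends to `theta` (pure red).
#'
#' @param alpha,beta Channel sensitivity to NIR and red light, `>= 0`.
#' @param lambda_,theta Plant-to-whiteboard reflectance ratio in NIR and red.
#' @param Nw,Rw Whiteboard NIR and red reflectance.
#' @return Scalar calibrated channel value.
#' @export
channel_value_model <- function(alpha, beta, lambda_, theta, Nw, Rw) {
  stopifnot(alpha >= 0, beta >= 0, Nw >= 0, Rw >= 0)
  den <- alpha * Nw + beta * Rw
  if (den <= 0) stop("channel purity model undefined: alpha*Nw + beta*Rw = 0")
  (alpha * lambda_ * Nw + beta * theta * Rw) / den
}

#' Per-channel NIR-to-red sensitivity ratio
#'
#' Mean effective sensitivity over the NIR window divided by the mean over
#' the red window, per channel. A zero NIR mean gives 0; a zero red mean with
#' positive NIR mean gives `Inf`.
#'
#' @param eff_sens A [sensitivity_set()].
#' @param red_window,nir_window [band_window()]s.
#' @return Named numeric vector `c(R, G, B)` of ratios.
#' @export
nir_red_ratio <- function(eff_sens, red_window, nir_window) {
  bm <- band_sensitivity_matrix(eff_sens, list(red = red_window, nir = nir_window))
  out <- numeric(3)
  for (ch in 1:3) {
    nirm <- bm[ch, "nir"]; redm <- bm[ch, "red"]
    if (nirm == 0 && redm == 0)
      stop("NIR-red ratio undefined: both band means are zero")
    out[ch] <- if (nirm == 0) 0 else if (redm == 0) Inf else nirm / redm
  }
  names(out) <- c("R", "G", "B")
  out
}

#' Camera system preset
#'
#' Bundles the NIR-sensitive sensor, its filter, the effective (filtered)
#' sensitivities and the system's red/NIR windows. Construction checks the
#' qualitative band-sensitivity structure of each system: for the long-pass
#' system the red-band sensitivities satisfy `j1 >> j2 > j3` (red channel
#' dominant); for the two-band-pass system `l1 >> l2 ~ l3` in the red band
#' and `m1 ~ m2 ~ m3` in the NIR band.
#'
#' @param name `"ncam_lp"` (long-pass, 580 nm cut-on) or `"ncam_tp"`
#'   (two-band-pass, 650/850 nm, FWHM 40 nm).
#' @param wavelength Wavelengths (nm); default [default_grid()].
#' @return Object of class `"ncam_camera"`: list with `name`, `sensor`,
#'   `filter`, `eff_sens`, `windows`, `band_matrix`.
#' @export
ncam_camera <- function(name = c("ncam_lp", "ncam_tp"),
                        wavelength = default_grid()) {
  name <- match.arg(name)
  sensor <- rgbn_sensitivities(wavelength)
  filt <- if (name == "ncam_lp") filter_spec("long_pass")
          else filter_spec("two_band_pass")
  eff <- apply_filter(sensor, filt)
  windows <- system_windows(if (name == "ncam_lp") "lp" else "tp")
  bm <- band_sensitivity_matrix(eff, windows)
  if (name == "ncam_lp") {
    j <- bm[, "red"]
    if (!(j[1] > 3 * j[2] && j[2] > j[3]))
      stop("long-pass red-band sensitivities violate j1 >> j2 > j3")
  } else {
    l <- bm[, "red"]; m <- bm[, "nir"]
    if (!(l[1] > 5 * max(l[2], l[3]) && abs(l[2] - l[3]) < 0.15 * l[1]))
      stop("two-band-pass red-band sensitivities violate l1 >> l2 ~ l3")
    if (max(m) - min(m) > 0.05 * max(m))
      stop("two-band-pass NIR-band sensitivities violate m1 ~ m2 ~ m3")
  }
  structure(list(name = name, sensor = sensor, filter = filt,
                 eff_sens = eff, windows = windows, band_matrix = bm),
            class = "ncam_camera")
}

#' @export
print.ncam_camera <- function(x, ...) {
  cat(sprintf("<ncam_camera> %s\nband-sensitivity matrix:\n", x$name))
  print(round(x$band_matrix, 4))
  invisible(x)
}

#' Write a curve (sensitivity channel, filter, spectrum) as two-column text
#'
#' @param wavelength,value Equal-length numeric vectors.
#' @param path Output file.
#' @export
write_curve <- function(wavelength, value, path) {
  utils::write.table(data.frame(wavelength_nm = wavelength, value = value),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column curve written by [write_curve()]
#' @param path Input file.
#' @return A [spectrum()].
#' @export
read_curve <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  spectrum(d[[1]], d[[2]])
}
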