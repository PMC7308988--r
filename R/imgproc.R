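# Image-processing chain: whiteboard calibration, segmentation (channel
# index for camera images, red-edge score for cubes), foreground averaging,
# and true-color rendering.

#' Whiteboard calibration
#'
#' Divides an image (3-plane array or hyperspectral cube) pixelwise by the
#' corresponding whiteboard image, yielding values on a reflectance-factor
#' scale (the whiteboard itself maps to 1). Whiteboard pixels at or near zero
#' are masked out as `NA`, with their count reported in the `n_invalid`
#' attribute.
#'
#' @param image Numeric array (`H x W x 3` or a cube).
#' @param white Whiteboard image of identical shape.
#' @param eps Whiteboard values `<= eps` are treated as invalid (default 1e-12).
#' @return Calibrated array of the same shape and class, attribute
#'   `n_invalid`.
#' @export
calibrate <- function(image, white, eps = 1e-12) {
  if (!identical(dim(image), dim(white)))
    stop("image and whiteboard shapes differ")
  bad <- unclass(white) <= eps
  if (all(bad)) stop("whiteboard image is entirely zero")
  den <- unclass(white)
  den[bad] <- NA_real_
  out <- array(unclass(image) / den, dim(image))
  if (!is.null(attr(image, "wavelength"))) {
    attr(out, "wavelength") <- attr(image, "wavelength")
    class(out) <- class(image)
  }
  if (!is.null(attr(image, "camera"))) attr(out, "camera") <- attr(image, "camera")
  attr(out, "n_invalid") <- sum(bad)
  out
}

#' Segment a camera image by the blue-red normalized index
#'
#' Computes `n = (Bc - Rc) / (Bc + Rc)` per pixel (0 where the denominator is
#' zero, so such pixels read as background at any positive threshold) and
#' keeps pixels with `n >= t`; background pixels are zeroed.
#'
#' @param image Calibrated `H x W x 3` array.
#' @param t Threshold (default 0.1, chosen to maximize truth-mask agreement
#'   on the default synthetic cohort).
#' @return Object of class `"segmented_image"`: list with `values`
#'   (background zeroed), `mask` (logical), `index` (the per-pixel `n`) and
#'   `threshold`.
#' @export
rgbn_segment <- function(image, t = 0.1) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("rgbn_segment expects an H x W x 3 image")
  d <- dim(image)
  B <- matrix(image[, , 3], d[1], d[2])
  R <- matrix(image[, , 1], d[1], d[2])
  den <- B + R
  n <- ifelse(is.finite(den) & den > 0, (B - R) / den, 0)
  mask <- !is.na(n) & n >= t
  vals <- unclass(image)
  vals[array(rep(!mask, 3), dim(image))] <- 0
  structure(list(values = vals, mask = mask, index = n, threshold = t),
            class = "segmented_image")
}

#' Segment a hyperspectral cube by its red-edge contrast
#'
#' Per-pixel red-edge score: mean reflectance over 750--800 nm minus mean
#' over 660--690 nm (a two-box convolution along the spectral axis).
#' Vegetation has a strong red edge and scores high; soil and whiteboard
#' score near zero. The mask keeps pixels with score `>= threshold`.
#'
#' @param cube An [hscube()] whose grid covers 660--800 nm.
#' @param threshold Score threshold (default 0.05).
#' @param red_band,nir_band Wavelength intervals (nm) for the two box means.
#' @return Logical mask matrix with the score matrix as attribute `score`.
#' @export
hsc_segment <- function(cube, threshold = 0.05,
                        red_band = c(660, 690), nir_band = c(750, 800)) {
  w <- attr(cube, "wavelength")
  ri <- w >= red_band[1] & w <= red_band[2]
  ni <- w >= nir_band[1] & w <= nir_band[2]
  if (!any(ri) || !any(ni))
    stop("cube grid does not cover the red-edge bands")
  m <- cube_matrix(cube)
  score <- rowMeans(m[, ni, drop = FALSE]) - rowMeans(m[, ri, drop = FALSE])
  d <- dim(cube)
  score <- matrix(score, d[1], d[2])
  structure(score >= threshold, score = score)
}

#' Average the foreground of a segmented image or masked cube
#'
#' @param x A `"segmented_image"` (per-channel means) or an [hscube()]
#'   (per-band mean spectrum; requires `mask`).
#' @param mask Logical matrix for cube input.
#' @return For camera images, a list with `means` (named `R`, `G`, `B`) and
#'   `n_pixels`; for cubes, a list with `spectrum` (a [spectrum()]) and
#'   `n_pixels`.
#' @export
mean_foreground <- function(x, mask = NULL) {
  if (inherits(x, "segmented_image")) {
    mask <- x$mask
    if (!any(mask)) stop("empty segmentation mask")
    keep <- as.vector(mask)
    m <- matrix(x$values, ncol = 3)
    means <- colMeans(m[keep, , drop = FALSE])
    names(means) <- c("R", "G", "B")
    return(list(means = means, n_pixels = sum(keep)))
  }
  if (inherits(x, "hscube")) {
    if (is.null(mask) || !any(mask)) stop("cube averaging needs a nonempty mask")
    m <- cube_matrix(x)
    sp <- colMeans(m[as.vector(mask), , drop = FALSE])
    return(list(spectrum = spectrum(attr(x, "wavelength"), pmax(sp, 0)),
                n_pixels = sum(mask)))
  }
  stop("mean_foreground expects a segmented_image or hscube")
}

#' True-color rendering of a hyperspectral cube
#'
#' Convolves each pixel spectrum with the sensitivities of a typical
#' (NIR-rejected) RGB camera and white-balances so a flat whiteboard spectrum
#' maps to equal channels.
#'
#' @param cube An [hscube()].
#' @param rgb_sens Visible-only [sensitivity_set()]; default
#'   [typical_rgb_sensitivities()] on the cube's grid.
#' @param white_value Whiteboard reflectance used for the balance (default 0.95).
#' @return `H x W x 3` array; the whiteboard maps to 1 in every channel.
#' @export
true_color <- function(cube, rgb_sens = NULL, white_value = 0.95) {
  w <- attr(cube, "wavelength")
  if (is.null(rgb_sens)) rgb_sens <- typical_rgb_sensitivities(w)
  if (any(rgb_sens$sens[w > 750, ] > 0.05))
    stop("true-color sensitivities must reject NIR")
  white <- simulate_channels(spectrum(w, rep(white_value, length(w))), rgb_sens)
  weights <- trapz_weights(w)
  vals <- cube_matrix(cube) %*% (rgb_sens$sens * weights)
  vals <- sweep(vals, 2, white, "/")
  d <- dim(cube)
  array(vals, c(d[1], d[2], 3))
}

#' Agreement between two masks
#'
#' Fraction of pixels on which two logical masks agree.
#' @param a,b Logical matrices of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
mask_agreement <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  mean(a == b)
}
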