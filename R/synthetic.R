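# Synthetic study generator: a 2x2 factorial (water x nitrogen) cohort of
# corn plants, each with a hyperspectral scene cube, two filtered-camera
# images, plus whiteboard reference images and a ground-truth table.

#' Cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: 14 replicates
#' of a 2x2 water-by-nitrogen factorial (56 plants); ground-truth NDVI drawn
#' from a Beta distribution moment-matched on support `[0.587, 0.749]` to
#' mean 0.686 and CV 0.058 (shape parameters about 1.79 and 1.14); lognormal
#' per-plant brightness modelling plant-height/illumination effects;
#' treatment-conditional nitrogen content (% dry mass, synthetic).
#'
#' @param replicates Plants per treatment cell (default 14).
#' @param ndvi_support Lower/upper NDVI bounds (default `c(0.587, 0.749)`).
#' @param ndvi_mean,ndvi_cv Target NDVI mean and coefficient of variation.
#' @param nitrogen_mean Named vector, mean % dry mass for `high` and `low`
#'   nitrogen treatments.
#' @param nitrogen_sd,nitrogen_min Nitrogen draw SD and lower clip.
#' @param brightness_sdlog Lognormal SD of per-plant brightness.
#' @param canopy_fraction Range of plant cover fraction per scene.
#' @param stress_nir_scale NIR plateau multiplier for drought-stressed plants.
#' @param pixel_jitter_sd Per-pixel multiplicative spectral jitter SD.
#' @param nir_tilt_sd Per-pixel NIR tilt SD (creates within-plant NDVI spread).
#' @param illumination_sdlog Per-pixel lognormal illumination noise of the
#'   camera render.
#' @param additive_sd Additive Gaussian camera noise SD (channel-value units).
#' @param image_size `c(height, width)` in pixels (default 48 x 64, a
#'   desk-scale stand-in for the full sensor).
#' @param wavelength Spectral grid (default [default_grid()]).
#' @param seed Master seed; every random stream derives from it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(replicates = 14,
                          ndvi_support = c(0.587, 0.749),
                          ndvi_mean = 0.686, ndvi_cv = 0.058,
                          nitrogen_mean = c(high = 3.0, low = 1.8),
                          nitrogen_sd = 0.3, nitrogen_min = 0.5,
                          brightness_sdlog = 0.25,
                          canopy_fraction = c(0.20, 0.40),
                          stress_nir_scale = 0.94,
                          pixel_jitter_sd = 0.02, nir_tilt_sd = 0.03,
                          illumination_sdlog = 0.02, additive_sd = 0.002,
                          image_size = c(48, 64),
                          wavelength = default_grid(),
                          seed = 20200605) {
  stopifnot(replicates >= 1, length(ndvi_support) == 2,
            ndvi_support[1] > -1, ndvi_support[2] < 1,
            ndvi_support[1] < ndvi_support[2],
            all(image_size >= 16))
  if (ndvi_mean <= ndvi_support[1] || ndvi_mean >= ndvi_support[2])
    stop("ndvi_mean must lie inside the support")
  cfg <- list(replicates = replicates, ndvi_support = ndvi_support,
              ndvi_mean = ndvi_mean, ndvi_cv = ndvi_cv,
              nitrogen_mean = nitrogen_mean, nitrogen_sd = nitrogen_sd,
              nitrogen_min = nitrogen_min,
              brightness_sdlog = brightness_sdlog,
              canopy_fraction = canopy_fraction,
              stress_nir_scale = stress_nir_scale,
              pixel_jitter_sd = pixel_jitter_sd, nir_tilt_sd = nir_tilt_sd,
              illumination_sdlog = illumination_sdlog,
              additive_sd = additive_sd,
              image_size = image_size,
              wavelength = as.numeric(wavelength_grid(wavelength)),
              seed = seed)
  class(cfg) <- "cohort_config"
  cfg
}

#' Beta shape parameters matching the configured NDVI moments
#' @noRd
ndvi_beta_shapes <- function(config) {
  lo <- config$ndvi_support[1]; hi <- config$ndvi_support[2]
  m <- (config$ndvi_mean - lo) / (hi - lo)
  s <- config$ndvi_cv * config$ndvi_mean / (hi - lo)
  v <- s^2
  if (v >= m * (1 - m)) stop("NDVI mean/CV incompatible with a Beta on this support")
  k <- m * (1 - m) / v - 1
  c(shape1 = m * k, shape2 = (1 - m) * k)
}

#' Sample per-plant parameters for the cohort
#'
#' Produces `replicates x 4` plant specifications. Ground-truth NDVI is drawn
#' from the scaled Beta by stratified inversion (one draw per probability
#' stratum, randomly assigned to plants), which keeps the cohort-level mean
#' and CV close to the configured values at n = 56 while preserving the
#' marginal distribution. Nitrogen content is drawn from
#' treatment-conditional normals; brightness is lognormal. Deterministic
#' given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with one row per plant: `plant_id`, `water`,
#'   `nitrogen_level`, `target_ndvi`, `nitrogen`, `brightness`,
#'   `canopy_fraction`.
#' @export
sample_cohort_params <- function(config = cohort_config()) {
  shapes <- ndvi_beta_shapes(config)
  lo <- config$ndvi_support[1]; hi <- config$ndvi_support[2]
  design <- expand.grid(rep = seq_len(config$replicates),
                        water = c("well_watered", "drought"),
                        nitrogen_level = c("high", "low"),
                        stringsAsFactors = FALSE)
  n <- nrow(design)
  with_seed(config$seed, {
    strata <- sample.int(n)
    u <- (strata - stats::runif(n)) / n
    ndvi <- lo + (hi - lo) * stats::qbeta(u, shapes[1], shapes[2])
    nitrogen <- pmax(config$nitrogen_min,
                     stats::rnorm(n, config$nitrogen_mean[design$nitrogen_level],
                                  config$nitrogen_sd))
    brightness <- stats::rlnorm(n, 0, config$brightness_sdlog)
    canopy <- stats::runif(n, config$canopy_fraction[1], config$canopy_fraction[2])
    data.frame(
      plant_id = sprintf("plant_%02d", seq_len(n)),
      water = design$water,
      nitrogen_level = design$nitrogen_level,
      target_ndvi = ndvi,
      nitrogen = as.numeric(nitrogen),
      brightness = brightness,
      canopy_fraction = canopy,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a plant reflectance spectrum with an exact NDVI
#'
#' Piecewise vegetation template: low blue, a green bump near 550 nm, a
#' chlorophyll-controlled red trough near 680 nm, a sigmoid red edge between
#' 700 and 750 nm, and an NIR plateau. The red-trough level is solved in
#' closed form so that [ndvi_from_spectrum()] returns `target_ndvi` to within
#' 1e-9. Nitrogen shifts the red-edge inflection (about +5 nm per % dry mass
#' around 2.4%), concentrating the nitrogen signal in 700--800 nm; drought
#' stress scales the NIR plateau.
#'
#' @param target_ndvi Desired NDVI, `|target_ndvi| < 1`.
#' @param nitrogen Nitrogen content in % dry mass (default 2.4).
#' @param stress Logical; drought-stressed plant.
#' @param wavelength Spectral grid.
#' @param nir_plateau Unstressed NIR plateau reflectance (default 0.45).
#' @param stress_nir_scale NIR plateau multiplier applied when `stress`.
#' @param green_amplitude Green bump height above the trough (default 0.09).
#' @return A [spectrum()].
#' @export
generate_plant_spectrum <- function(target_ndvi, nitrogen = 2.4, stress = FALSE,
                                    wavelength = default_grid(),
                                    nir_plateau = 0.45,
                                    stress_nir_scale = 0.94,
                                    green_amplitude = 0.09) {
  if (abs(target_ndvi) >= 1) stop("target NDVI must lie in (-1, 1)")
  w <- as.numeric(wavelength_grid(wavelength))
  P <- nir_plateau * if (isTRUE(stress)) stress_nir_scale else 1
  edge_pos <- 715 + 5 * (nitrogen - 2.4)
  edge_width <- 5
  q <- stats::plogis((w - edge_pos) / edge_width)       # red-edge sigmoid
  g <- green_amplitude * exp(-((w - 550)^2) / (2 * 30^2))
  # refl(w; r) = r + g + (P - r) * q   is linear in the trough level r, so
  # both NDVI band means are linear in r and the target is solved exactly.
  band <- function(v, ctr) {
    keep <- w >= ctr - 5 & w <= ctr + 5
    mean(v[keep])
  }
  t680 <- list(c = band(g + P * q, 680), d = band(1 - q, 680))
  t850 <- list(c = band(g + P * q, 850), d = band(1 - q, 850))
  t <- target_ndvi
  r <- (t850$c - t680$c - t * (t850$c + t680$c)) /
       (t * (t850$d + t680$d) - t850$d + t680$d)
  if (!is.finite(r) || r <= 0 || r >= P)
    stop("target NDVI unattainable for the template bounds")
  spectrum(w, r + g + (P - r) * q)
}

#' Whiteboard and background reference spectra
#'
#' The whiteboard is a flat 0.95 reflectance panel; the background is a low,
#' gently rising soil-like curve with essentially no red edge.
#'
#' @param wavelength Spectral grid.
#' @return List of two [spectrum()]s: `whiteboard` and `background`.
#' @export
generate_reference_spectra <- function(wavelength = default_grid()) {
  w <- as.numeric(wavelength_grid(wavelength))
  list(whiteboard = spectrum(w, rep(0.95, length(w))),
       background = spectrum(w, 0.20 + 0.04 * (w - min(w)) / diff(range(w))))
}

#' Elliptical blob plant mask covering approximately `canopy_fraction`
#' @noRd
plant_mask <- function(height, width, canopy_fraction) {
  if (canopy_fraction <= 0) stop("canopy fraction must be positive")
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  # semi-axes sized so the ellipse area is canopy_fraction * height * width
  a <- height / 2 * sqrt(canopy_fraction * 4 / pi)
  b <- width / 2 * sqrt(canopy_fraction * 4 / pi)
  theta <- atan2(rows - cy, cols - cx)
  wobble <- 1 + 0.12 * sin(3 * theta + stats::runif(1, 0, 2 * pi)) +
    0.08 * cos(5 * theta + stats::runif(1, 0, 2 * pi))
  ((rows - cy) / a)^2 + ((cols - cx) / b)^2 <= wobble^2
}

#' Render one synthetic scene (hyperspectral cube + truth mask)
#'
#' Plant pixels carry per-pixel jittered copies of the plant spectrum
#' (multiplicative amplitude jitter plus an NIR tilt that spreads per-pixel
#' NDVI); the red-trough region is then rescaled by a common factor, found by
#' root solving, so the plant-pixel mean NDVI equals the plant's target to
#' within 1e-6. Background pixels carry the soil spectrum with amplitude
#' jitter. The whole cube is multiplied by the plant's brightness factor.
#'
#' @param plant One row of [sample_cohort_params()] output (data.frame or list).
#' @param config A [cohort_config()].
#' @param seed Seed for this scene's random streams.
#' @return Object of class `"ncam_scene"`: list with `cube` ([hscube()]),
#'   `mask` (logical matrix, plant = TRUE) and `plant` (the spec).
#' @export
render_scene <- function(plant, config = cohort_config(),
                         seed = config$seed) {
  w <- config$wavelength
  H <- config$image_size[1]; W <- config$image_size[2]
  refs <- generate_reference_spectra(w)
  base <- generate_plant_spectrum(
    plant$target_ndvi, plant$nitrogen, plant$water == "drought", w,
    stress_nir_scale = config$stress_nir_scale)
  with_seed(seed, {
    mask <- plant_mask(H, W, plant$canopy_fraction)
    npx <- H * W
    np <- sum(mask)
    if (np == 0) stop("empty plant mask")
    amp <- exp(stats::rnorm(npx, 0, config$pixel_jitter_sd))
    tilt <- stats::rnorm(np, 0, config$nir_tilt_sd)
    tilt_shape <- stats::plogis((w - 720) / 10)
    # plant pixel matrix: np x bands
    pv <- outer(amp[as.vector(mask)], base$value) *
      (1 + outer(tilt, tilt_shape))
    pv[pv < 0] <- 0
    # enforce the plant-mean NDVI by scaling the red-trough region
    red_w <- exp(-((w - 680)^2) / (2 * 25^2))
    b680i <- w >= 675 & w <= 685
    b850i <- w >= 845 & w <= 855
    a680 <- rowMeans(pv[, b680i, drop = FALSE])
    c680 <- rowMeans(sweep(pv[, b680i, drop = FALSE], 2, red_w[b680i], "*"))
    a850 <- rowMeans(pv[, b850i, drop = FALSE])
    c850 <- rowMeans(sweep(pv[, b850i, drop = FALSE], 2, red_w[b850i], "*"))
    mean_ndvi <- function(f) {
      b680 <- a680 + (f - 1) * c680
      b850 <- a850 + (f - 1) * c850
      mean((b850 - b680) / (b850 + b680))
    }
    f <- stats::uniroot(function(f) mean_ndvi(f) - plant$target_ndvi,
                        c(0.05, 5), tol = 1e-12)$root
    pv <- pv * (1 + (f - 1) * outer(rep(1, np), red_w))
    bg <- outer(amp[!as.vector(mask)], refs$background$value)
    m <- matrix(0, npx, length(w))
    m[as.vector(mask), ] <- pv
    m[!as.vector(mask), ] <- bg
    m <- m * plant$brightness
    structure(list(cube = hscube(array(m, c(H, W, length(w))), w),
                   mask = mask, plant = as.list(plant)),
              class = "ncam_scene")
  })
}

#' Render a camera image of a scene
#'
#' Applies [simulate_channels()] per pixel (as one matrix product), then
#' multiplicative lognormal illumination noise and additive Gaussian noise,
#' clipping at zero. Optionally quantizes to 16-bit counts using the camera's
#' whiteboard-referenced gain.
#'
#' @param scene An `"ncam_scene"` (or an [hscube()]).
#' @param camera An [ncam_camera()] on the same grid.
#' @param config A [cohort_config()] supplying the noise levels.
#' @param seed Seed for the noise streams.
#' @param noise Logical; disable to get the exact per-pixel channel integrals.
#' @param quantize Logical; return integer counts in `[0, 65535]`.
#' @return `height x width x 3` numeric array with attribute `camera`.
#' @export
render_ncam_image <- function(scene, camera, config = cohort_config(),
                              seed = config$seed, noise = TRUE,
                              quantize = FALSE) {
  cube <- if (inherits(scene, "ncam_scene")) scene$cube else scene
  w <- attr(cube, "wavelength")
  if (length(w) != length(camera$eff_sens$wavelength) ||
      any(abs(w - camera$eff_sens$wavelength) > 1e-9))
    stop("camera grid does not match the cube grid")
  d <- dim(cube)
  weights <- trapz_weights(w)
  vals <- cube_matrix(cube) %*% (camera$eff_sens$sens * weights)
  if (noise) {
    vals <- with_seed(seed, {
      ill <- exp(stats::rnorm(nrow(vals), 0, config$illumination_sdlog))
      v <- vals * ill + matrix(stats::rnorm(length(vals), 0, config$additive_sd),
                               nrow(vals))
      v[v < 0] <- 0
      v
    })
  }
  if (quantize) {
    gain <- camera_gain(camera)
    vals <- pmin(pmax(round(vals * gain), 0), 65535)
  }
  structure(array(vals, c(d[1], d[2], 3)), camera = camera$name)
}

#' Whiteboard-referenced digital gain of a camera: a flat 0.95 panel maps to
#' about 80% of full scale in its brightest channel.
#' @noRd
camera_gain <- function(camera) {
  white <- spectrum(camera$eff_sens$wavelength,
                    rep(0.95, length(camera$eff_sens$wavelength)))
  0.8 * 65535 / max(simulate_channels(white, camera$eff_sens))
}

#' Generate the full synthetic cohort
#'
#' Scenes, camera images (long-pass and two-band-pass systems), whiteboard
#' references for the three instruments, and the ground-truth table. The
#' image count is `plants x 3 + 3` (each plant's hyperspectral cube plus two
#' camera images, and three whiteboards). All randomness derives from
#' `config$seed` through per-plant sub-seeds, so regeneration is exact and
#' order-independent.
#'
#' @param config A [cohort_config()].
#' @param keep_cubes Keep each scene's cube in the returned object (default
#'   TRUE). With `FALSE` only masks, camera images and truth are retained.
#' @return Object of class `"ncam_cohort"`: list with `scenes`, `images`
#'   (per plant, `lp` and `tp`), `whiteboards` (`hsc` cube, `lp`, `tp`
#'   images), `truth` (data.frame), `cameras`, `config`, `n_images`.
#' @export
generate_cohort <- function(config = cohort_config(), keep_cubes = TRUE) {
  specs <- sample_cohort_params(config)
  cams <- list(lp = ncam_camera("ncam_lp", config$wavelength),
               tp = ncam_camera("ncam_tp", config$wavelength))
  scenes <- vector("list", nrow(specs))
  images <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sc <- render_scene(specs[i, ], config, seed = split_seed(config$seed, i, 1L))
    img <- list(
      lp = render_ncam_image(sc, cams$lp, config, seed = split_seed(config$seed, i, 2L)),
      tp = render_ncam_image(sc, cams$tp, config, seed = split_seed(config$seed, i, 3L)))
    if (!keep_cubes) sc$cube <- NULL
    scenes[[i]] <- sc
    images[[i]] <- img
  }
  names(scenes) <- names(images) <- specs$plant_id
  wb <- render_whiteboards(config, cams)
  truth <- specs[, c("plant_id", "water", "nitrogen_level", "target_ndvi", "nitrogen")]
  names(truth)[4] <- "ndvi"
  structure(list(scenes = scenes, images = images, whiteboards = wb,
                 truth = truth, specs = specs, cameras = cams,
                 config = config,
                 n_images = nrow(specs) * 3L + 3L),
            class = "ncam_cohort")
}

#' Whiteboard scene cube and camera images
#' @noRd
render_whiteboards <- function(config, cams) {
  w <- config$wavelength
  H <- config$image_size[1]; W <- config$image_size[2]
  white <- generate_reference_spectra(w)$whiteboard
  cube <- with_seed(split_seed(config$seed, 0L, 4L), {
    amp <- exp(stats::rnorm(H * W, 0, 0.005))
    hscube(array(outer(amp, white$value), c(H, W, length(w))), w)
  })
  list(hsc = cube,
       lp = render_ncam_image(cube, cams$lp, config,
                              seed = split_seed(config$seed, 0L, 5L)),
       tp = render_ncam_image(cube, cams$tp, config,
                              seed = split_seed(config$seed, 0L, 6L)))
}

#' @export
print.ncam_cohort <- function(x, ...) {
  cat(sprintf("<ncam_cohort> %d plants, %d images (%d x %d px, %d bands), seed %s\n",
              nrow(x$truth), x$n_images, x$config$image_size[1],
              x$config$image_size[2], length(x$config$wavelength),
              format(x$config$seed)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Camera images as 16-bit TIFF (`{plant_id}_{lp|tp}.tif`), scene cubes as
#' ENVI header + float32 BSQ binary (`{plant_id}_hsc.hdr/.dat`), whiteboards
#' as `white_{hsc|lp|tp}`, and the truth table as `truth.csv`.
#'
#' @param cohort An [generate_cohort()] result (with cubes retained).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  gains <- lapply(cohort$cameras, camera_gain)
  write_img <- function(img, cam, path) {
    counts <- pmin(pmax(img * gains[[cam]], 0), 65535) / 65535
    tiff::writeTIFF(counts, path, bits.per.sample = 16)
    path
  }
  for (id in cohort$truth$plant_id) {
    files <- c(files,
      write_img(cohort$images[[id]]$lp, "lp", file.path(dir, paste0(id, "_lp.tif"))),
      write_img(cohort$images[[id]]$tp, "tp", file.path(dir, paste0(id, "_tp.tif"))))
    if (!is.null(cohort$scenes[[id]]$cube))
      files <- c(files, write_envi(cohort$scenes[[id]]$cube,
                                   file.path(dir, paste0(id, "_hsc"))))
  }
  files <- c(files,
    write_img(cohort$whiteboards$lp, "lp", file.path(dir, "white_lp.tif")),
    write_img(cohort$whiteboards$tp, "tp", file.path(dir, "white_tp.tif")),
    write_envi(cohort$whiteboards$hsc, file.path(dir, "white_hsc")))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(c(files, file.path(dir, "truth.csv")))
}
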