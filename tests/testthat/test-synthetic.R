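# Synthetic cohort generator: plant parameters, spectra, scenes, images.

test_that("cohort parameters honour the factorial design and NDVI support", {
  specs <- sample_cohort_params(cohort_config())
  expect_equal(nrow(specs), 56)
  expect_equal(unname(table(specs$water, specs$nitrogen_level)),
               matrix(14, 2, 2))
  expect_true(all(specs$target_ndvi >= 0.587 & specs$target_ndvi <= 0.749))
  expect_true(all(specs$nitrogen > 0))
  expect_true(all(specs$brightness > 0))
  # determinism: same seed, identical draw
  expect_identical(specs, sample_cohort_params(cohort_config()))
  # different seed, different draw
  expect_false(identical(specs$target_ndvi,
                         sample_cohort_params(cohort_config(seed = 7))$target_ndvi))
})

test_that("plant spectra hit their target NDVI exactly and have a red edge", {
  for (target in c(0.59, 0.686, 0.748)) {
    s <- generate_plant_spectrum(target)
    expect_equal(ndvi_from_spectrum(s), target, tolerance = 1e-9)
    at <- function(nm) s$value[which.min(abs(s$wavelength - nm))]
    expect_gt(at(750), at(680))
  }
  expect_error(generate_plant_spectrum(0.9999), "unattainable")
  expect_error(generate_plant_spectrum(1.2), "\\(-1, 1\\)")
})

test_that("nitrogen moves the red-edge region without touching the NDVI bands", {
  hi <- generate_plant_spectrum(0.686, nitrogen = 3.0)
  lo <- generate_plant_spectrum(0.686, nitrogen = 1.8)
  w <- hi$wavelength
  edge <- w >= 700 & w <= 800
  expect_gt(abs(mean(hi$value[edge]) - mean(lo$value[edge])), 0.005)
  # both still satisfy the same NDVI target
  expect_equal(ndvi_from_spectrum(hi), ndvi_from_spectrum(lo), tolerance = 1e-9)
  # the signal is invisible to the two-band-pass windows
  tp <- system_windows("tp")
  nirw <- w >= tp$nir$lo_nm & w < tp$nir$hi_nm
  redw <- w >= tp$red$lo_nm & w < tp$red$hi_nm
  expect_lt(abs(mean(hi$value[nirw]) - mean(lo$value[nirw])), 1e-3)
  expect_lt(abs(mean(hi$value[redw]) - mean(lo$value[redw])) /
              mean(lo$value[redw]), 0.05)
})

test_that("reference spectra look like a whiteboard and a soil background", {
  refs <- generate_reference_spectra()
  expect_gt(min(refs$whiteboard$value), 0.9)
  expect_lt(abs(ndvi_from_spectrum(refs$whiteboard)), 0.01)
  expect_lt(ndvi_from_spectrum(refs$background), 0.3)
})

test_that("rendered scenes cover the canopy fraction and hit the mean NDVI", {
  cfg <- small_config()
  specs <- sample_cohort_params(cfg)
  sc <- render_scene(specs[1, ], cfg, seed = 123)
  frac <- mean(sc$mask)
  expect_lt(abs(frac - specs$canopy_fraction[1]) / specs$canopy_fraction[1], 0.2)
  m <- cube_matrix(sc$cube)
  w <- attr(sc$cube, "wavelength")
  ndvi_px <- function(rows) {
    b850 <- rowMeans(rows[, w >= 845 & w <= 855, drop = FALSE])
    b680 <- rowMeans(rows[, w >= 675 & w <= 685, drop = FALSE])
    (b850 - b680) / (b850 + b680)
  }
  plant_ndvi <- ndvi_px(m[as.vector(sc$mask), , drop = FALSE])
  bg_ndvi <- ndvi_px(m[!as.vector(sc$mask), , drop = FALSE])
  expect_equal(mean(plant_ndvi), specs$target_ndvi[1], tolerance = 1e-6)
  expect_true(all(bg_ndvi < mean(plant_ndvi)))
})

test_that("noise-free camera rendering equals the per-pixel channel integrals", {
  cfg <- small_config()
  specs <- sample_cohort_params(cfg)
  sc <- render_scene(specs[2, ], cfg, seed = 5)
  cam <- ncam_camera("ncam_lp")
  img <- render_ncam_image(sc, cam, cfg, noise = FALSE)
  w <- attr(sc$cube, "wavelength")
  for (px in list(c(1, 1), c(10, 20), c(12, 16))) {
    ref <- simulate_channels(spectrum(w, sc$cube[px[1], px[2], ]), cam$eff_sens)
    expect_equal(unname(img[px[1], px[2], ]), unname(ref), tolerance = 1e-12)
  }
  # doubling the scene brightness doubles every channel (linearity)
  sc2 <- sc
  sc2$cube <- hscube(unclass(sc$cube) * 2, w)
  img2 <- render_ncam_image(sc2, cam, cfg, noise = FALSE)
  expect_equal(unclass(img2), unclass(img) * 2, tolerance = 1e-12)
  # quantized output is integer counts within the 16-bit range
  imq <- render_ncam_image(sc, cam, cfg, seed = 5, quantize = TRUE)
  expect_true(all(imq >= 0 & imq <= 65535))
  expect_true(all(imq == round(imq)))
})

test_that("the generated cohort has the documented structure and is reproducible", {
  cfg <- small_config()
  cohort <- generate_cohort(cfg)
  n <- nrow(cohort$truth)
  expect_equal(n, 12)
  expect_equal(cohort$n_images, n * 3 + 3)
  expect_named(cohort$whiteboards, c("hsc", "lp", "tp"))
  expect_s3_class(cohort$whiteboards$hsc, "hscube")
  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort$truth, cohort2$truth)
  expect_equal(cohort$images[[3]]$tp, cohort2$images[[3]]$tp)
})

test_that("a cohort writes TIFF/ENVI/CSV files with the documented naming", {
  cfg <- cohort_config(replicates = 1, image_size = c(16, 16))
  cohort <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(cohort, dir)
  files <- list.files(dir)
  expect_true(all(c("plant_01_lp.tif", "plant_01_tp.tif", "plant_01_hsc.hdr",
                    "plant_01_hsc.dat", "white_lp.tif", "white_tp.tif",
                    "white_hsc.hdr", "truth.csv") %in% files))
  expect_equal(sum(grepl("\\.tif$", files)), 2 * 4 + 2)
  back <- read_envi(file.path(dir, "plant_01_hsc"))
  expect_equal(unclass(back), unclass(cohort$scenes[[1]]$cube), tolerance = 1e-5)
  tr <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(tr$plant_id, cohort$truth$plant_id)
  unlink(dir, recursive = TRUE)
})

test_that("cohort NDVI statistics track the configured Beta moments across seeds", {
  means <- cvs <- numeric(5)
  for (i in 1:5) {
    specs <- sample_cohort_params(cohort_config(seed = 1000 + i))
    means[i] <- mean(specs$target_ndvi)
    cvs[i] <- sd(specs$target_ndvi) / means[i]
  }
  expect_true(all(abs(means - 0.686) < 0.011))
  expect_true(all(abs(cvs - 0.058) < 0.006))
})
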