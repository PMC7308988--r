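# End-to-end virtual study runner: generate the cohort, process every image,
# fit and cross-validate the estimators, and assemble the report.

#' Study configuration
#'
#' @param cohort A [cohort_config()].
#' @param rgbn_threshold Segmentation threshold for camera images (see
#'   [rgbn_segment()]).
#' @param hsc_threshold Red-edge score threshold for cubes (see
#'   [hsc_segment()]).
#' @param ndvi_models NDVI estimator families to cross-validate per camera
#'   (the formula baseline is always included).
#' @param run_nitrogen Also fit the nitrogen models (camera MLR with
#'   interaction, cube PLSR).
#' @param plsr_lv Latent variables for the nitrogen PLSR (default 3).
#' @return List of class `"study_config"`.
#' @export
study_config <- function(cohort = cohort_config(),
                         rgbn_threshold = 0.1, hsc_threshold = 0.05,
                         ndvi_models = c("mlr", "gp_matern", "svr_quadratic"),
                         run_nitrogen = TRUE, plsr_lv = 3) {
  stopifnot(inherits(cohort, "cohort_config"), length(ndvi_models) >= 1)
  structure(list(cohort = cohort, rgbn_threshold = rgbn_threshold,
                 hsc_threshold = hsc_threshold,
                 ndvi_models = ndvi_models, run_nitrogen = run_nitrogen,
                 plsr_lv = plsr_lv),
            class = "study_config")
}

#' Run the virtual study end to end
#'
#' Generates the synthetic cohort (streaming one scene at a time), calibrates
#' every image against its whiteboard, segments plants, averages foreground
#' channels and spectra, derives the hyperspectral NDVI ground truth, then
#' runs leave-one-out cross-validation of the configured estimators per
#' camera plus the formula baseline, the nitrogen models, agreement analysis,
#' and cohort statistics. Deterministic given the cohort seed.
#'
#' @param config A [study_config()].
#' @return Object of class `"ncam_study"`; see the fields in the examples of
#'   `print()` and `summary()`.
#' @export
run_study <- function(config = study_config()) {
  cc <- config$cohort
  specs <- sample_cohort_params(cc)
  n <- nrow(specs)
  cams <- list(lp = ncam_camera("ncam_lp", cc$wavelength),
               tp = ncam_camera("ncam_tp", cc$wavelength))
  wb <- render_whiteboards(cc, cams)

  raw_means <- list(lp = matrix(NA_real_, n, 3, dimnames = list(specs$plant_id, c("R", "G", "B"))),
                    tp = matrix(NA_real_, n, 3, dimnames = list(specs$plant_id, c("R", "G", "B"))))
  spectra <- matrix(NA_real_, n, length(cc$wavelength),
                    dimnames = list(specs$plant_id, NULL))
  ndvi_hsc <- numeric(n)
  agreement <- matrix(NA_real_, n, 3,
                      dimnames = list(specs$plant_id, c("lp", "tp", "hsc")))

  for (i in seq_len(n)) {
    scene <- render_scene(specs[i, ], cc, seed = split_seed(cc$seed, i, 1L))
    for (cam in c("lp", "tp")) {
      img <- render_ncam_image(scene, cams[[cam]], cc,
                               seed = split_seed(cc$seed, i,
                                                 if (cam == "lp") 2L else 3L))
      cal <- calibrate(img, wb[[cam]])
      seg <- rgbn_segment(cal, config$rgbn_threshold)
      raw_means[[cam]][i, ] <- mean_foreground(seg)$means
      agreement[i, cam] <- mask_agreement(seg$mask, scene$mask)
    }
    cal_cube <- calibrate(scene$cube, wb$hsc)
    hmask <- hsc_segment(cal_cube, config$hsc_threshold)
    agreement[i, "hsc"] <- mask_agreement(hmask, scene$mask)
    fg <- mean_foreground(cal_cube, hmask)
    spectra[i, ] <- fg$spectrum$value
    ndvi_hsc[i] <- ndvi_from_spectrum(fg$spectrum)
  }

  truth <- specs[, c("plant_id", "water", "nitrogen_level", "target_ndvi", "nitrogen")]
  names(truth)[4] <- "ndvi"
  cohort_stats <- cohort_summary(truth$ndvi)
  channel_skewness <- lapply(raw_means, function(m) apply(m, 2, skewness))

  ndvi <- list()
  ba <- list()
  for (cam in c("lp", "tp")) {
    feats <- channel_sum_normalize(raw_means[[cam]])
    X <- as.matrix(feats)
    reports <- list()
    preds <- list()
    for (fam in config$ndvi_models) {
      p <- loocv(X, ndvi_hsc, family = fam)
      preds[[fam]] <- as.numeric(p)
      reports[[fam]] <- regression_metrics(ndvi_hsc, preds[[fam]],
                                           label = paste(cam, fam, sep = "-"))
    }
    pf <- typical_formula_ndvi(raw_means[[cam]][, "B"], raw_means[[cam]][, "R"])
    preds[["formula"]] <- pf
    reports[["formula"]] <- regression_metrics(ndvi_hsc, pf,
                                               label = paste(cam, "formula", sep = "-"))
    if ("mlr" %in% names(preds))
      ba[[cam]] <- bland_altman(preds[["mlr"]], ndvi_hsc)
    ndvi[[cam]] <- list(features = feats, predictions = preds,
                        metrics = reports,
                        comparison = compare_methods(reports))
  }

  nitrogen <- NULL
  if (isTRUE(config$run_nitrogen)) {
    nitrogen <- list()
    for (cam in c("lp", "tp")) {
      X <- as.matrix(channel_sum_normalize(raw_means[[cam]]))
      p <- loocv(X, truth$nitrogen, family = "mlr", interaction = TRUE)
      nitrogen[[cam]] <- list(
        predictions = as.numeric(p),
        metrics = regression_metrics(truth$nitrogen, as.numeric(p),
                                     label = paste(cam, "mlr-interaction", sep = "-")))
    }
    pp <- loocv(spectra, truth$nitrogen, family = "plsr", n_lv = config$plsr_lv,
                preprocess = fit_spectra_preprocessor)
    nitrogen$hsc <- list(
      predictions = as.numeric(pp),
      metrics = regression_metrics(truth$nitrogen, as.numeric(pp),
                                   label = "hsc-plsr"))
  }

  structure(list(config = config, truth = truth, cohort_stats = cohort_stats,
                 raw_means = raw_means, channel_skewness = channel_skewness,
                 spectra = spectra, ndvi_hsc = ndvi_hsc, ndvi = ndvi,
                 bland_altman = ba, nitrogen = nitrogen,
                 mask_agreement = agreement,
                 seed = cc$seed),
            class = "ncam_study")
}

#' @export
print.ncam_study <- function(x, ...) {
  cat(sprintf("<ncam_study> %d plants, seed %s\n", nrow(x$truth),
              format(x$seed)))
  cat(sprintf("ground-truth NDVI: mean %.3f, CV %.3f, range [%.3f, %.3f]\n",
              x$cohort_stats$mean, x$cohort_stats$coefficient_of_variation,
              x$cohort_stats$minimum, x$cohort_stats$maximum))
  for (cam in names(x$ndvi)) {
    cat(sprintf("\nNDVI estimators, %s camera:\n", cam))
    for (r in x$ndvi[[cam]]$metrics) print(r)
  }
  if (!is.null(x$nitrogen)) {
    cat("\nnitrogen estimators:\n")
    for (r in x$nitrogen) print(r$metrics)
  }
  invisible(x)
}

#' @export
summary.ncam_study <- function(object, ...) {
  print(object)
  cat("\nBland-Altman (MLR vs hyperspectral ground truth):\n")
  for (cam in names(object$bland_altman)) {
    cat(cam, ": "); print(object$bland_altman[[cam]])
  }
  cat(sprintf("\nmean mask agreement: lp %.4f, tp %.4f, hsc %.4f\n",
              mean(object$mask_agreement[, "lp"]),
              mean(object$mask_agreement[, "tp"]),
              mean(object$mask_agreement[, "hsc"])))
  invisible(object)
}

#' Serialize a study report to JSON
#'
#' Writes the metric tables, cohort statistics, agreement summaries and
#' provenance (seed, key configuration) of a study to a JSON file.
#'
#' @param study An `"ncam_study"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(study, path) {
  metr <- function(r) r[c("r2", "rmse", "mae", "mpe", "n", "label")]
  rep <- list(
    seed = study$seed,
    n_plants = nrow(study$truth),
    cohort_ndvi = unclass(study$cohort_stats),
    ndvi = lapply(study$ndvi, function(cam) lapply(cam$metrics, metr)),
    nitrogen = if (!is.null(study$nitrogen))
      lapply(study$nitrogen, function(m) metr(m$metrics)),
    bland_altman = lapply(study$bland_altman, function(b)
      b[c("bias", "loa_lower", "loa_upper", "frac_within", "n")]),
    mask_agreement = as.list(colMeans(study$mask_agreement)),
    channel_skewness = study$channel_skewness,
    config = list(
      rgbn_threshold = study$config$rgbn_threshold,
      hsc_threshold = study$config$hsc_threshold,
      image_size = study$config$cohort$image_size,
      replicates = study$config$cohort$replicates)
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
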