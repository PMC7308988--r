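# Camera forward model: filters, channel responses, band matrices, purity.

test_that("long-pass transmission is a step at the cutoff", {
  g <- default_grid()
  tr <- make_filter(filter_spec("long_pass"), g)
  expect_lt(tr[which.min(abs(g - 450))], 0.01)
  expect_gt(tr[which.min(abs(g - 800))], 0.99)
  expect_true(all(tr >= 0 & tr <= 1))
})

test_that("two-band-pass passbands have the stated centres and FWHM", {
  g <- seq(400, 1000, by = 0.5)   # fine grid so the probe points are exact
  spec <- filter_spec("two_band_pass")
  tr <- make_filter(spec, g)
  at <- function(nm) tr[which.min(abs(g - nm))]
  expect_equal(at(650), 1, tolerance = 1e-6)
  expect_equal(at(850), 1, tolerance = 1e-6)
  # half peak at centre +/- FWHM/2
  expect_equal(at(650 - 20), 0.5, tolerance = 1e-6)
  expect_equal(at(650 + 20), 0.5, tolerance = 1e-6)
  expect_equal(at(850 + 20), 0.5, tolerance = 1e-6)
  expect_lt(at(750), 0.01)
  expect_error(make_filter(filter_spec("two_band_pass", centers_nm = c(650, 1200)), g),
               "outside")
})

test_that("applying a filter is a pointwise product that never increases response", {
  s <- rgbn_sensitivities()
  allpass <- rep(1, length(s$wavelength))
  expect_equal(apply_filter(s, allpass)$sens, s$sens)
  expect_equal(max(apply_filter(s, allpass * 0)$sens), 0)
  tr <- make_filter(filter_spec("long_pass"), s$wavelength)
  f <- apply_filter(s, tr)
  expect_true(all(f$sens <= s$sens + 1e-12))
  i <- 100
  expect_equal(f$sens[i, 2], s$sens[i, 2] * tr[i])
  expect_error(apply_filter(s, tr[-1]), "does not match")
})

test_that("channel simulation is linear and respects grid matching", {
  g <- default_grid()
  cam <- ncam_camera("ncam_tp")
  zero <- spectrum(g, rep(0, 513))
  expect_equal(unname(simulate_channels(zero, cam$eff_sens)), c(0, 0, 0))
  set.seed(11)
  s1 <- spectrum(g, runif(513)); s2 <- spectrum(g, runif(513))
  lhs <- simulate_channels(spectrum(g, 2.5 * s1$value + s2$value), cam$eff_sens)
  rhs <- 2.5 * simulate_channels(s1, cam$eff_sens) + simulate_channels(s2, cam$eff_sens)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(simulate_channels(spectrum(g[-1], runif(512)), cam$eff_sens),
               "do not match")
})

test_that("a narrow 850 nm spectrum gives near-equal channels in the two-band-pass system", {
  g <- default_grid()
  cam <- ncam_camera("ncam_tp")
  v <- exp(-((g - 850)^2) / (2 * 4^2))
  ch <- simulate_channels(spectrum(g, v), cam$eff_sens)
  expect_lt(diff(range(ch)) / max(ch), 0.05)
})

test_that("band-sensitivity matrices show the documented channel structure", {
  g <- default_grid()
  flat <- sensitivity_set(g, matrix(1, 513, 3))
  bm <- band_sensitivity_matrix(flat, list(band_window(600, 700)))
  expect_equal(unname(bm[, 1]), c(1, 1, 1))
  lp <- ncam_camera("ncam_lp")
  j <- lp$band_matrix[, "red"]
  expect_gt(j[1], 3 * j[2])        # j1 >> j2
  expect_gt(j[2], j[3])            # j2 > j3
  tp <- ncam_camera("ncam_tp")
  l <- tp$band_matrix[, "red"]; m <- tp$band_matrix[, "nir"]
  expect_gt(l[1], 5 * max(l[2], l[3]))
  expect_lt(abs(l[2] - l[3]), 0.15 * l[1])
  expect_lt(diff(range(m)) / max(m), 0.05)
  expect_error(band_sensitivity_matrix(lp$eff_sens, list(band_window(1050, 1100))),
               "no grid points")
})

test_that("channel integrals match the band-matrix discretization for piecewise-flat spectra", {
  g <- default_grid()
  for (sys in c("lp", "tp")) {
    cam <- ncam_camera(if (sys == "lp") "ncam_lp" else "ncam_tp")
    win <- cam$windows
    v <- numeric(513)
    v[g >= win$red$lo_nm & g < win$red$hi_nm] <- 0.1
    v[g >= win$nir$lo_nm & g < win$nir$hi_nm] <- 0.5
    ch <- simulate_channels(spectrum(g, v), cam$eff_sens)
    widths <- vapply(win, function(wn) min(wn$hi_nm, max(g)) - wn$lo_nm, numeric(1))
    pred <- cam$band_matrix %*% (c(0.1, 0.5) * widths)
    expect_equal(unname(ch), unname(drop(pred)), tolerance = 0.05)
  }
})

test_that("the channel purity model matches its simplified form and limits", {
  # fixed worked example: alpha/beta = 9, lambda = 0.9, theta = 0.1
  expect_equal(channel_value_model(9, 1, 0.9, 0.1, 1, 1), 0.82)
  expect_equal(channel_value_model(3, 7, 0.4, 0.4, 2, 5), 0.4)   # lambda == theta
  expect_equal(channel_value_model(2, 2, 0.9, 0.1, 1, 1), 0.5)   # (lambda+theta)/2
  set.seed(99)
  for (k in 1:200) {
    a <- runif(1, 0.01, 10); b <- runif(1, 0.01, 10)
    l <- runif(1); t <- runif(1); Nw <- runif(1, 0.1, 1); Rw <- runif(1, 0.1, 1)
    full <- channel_value_model(a, b, l, t, Nw, Rw)
    simplified <- l + Rw * (t - l) / ((a / b) * Nw + Rw)
    expect_equal(full, simplified, tolerance = 1e-12)
  }
  # monotone nondecreasing in alpha/beta when lambda > theta, with the limits
  ratios <- 10^seq(-4, 4, length.out = 30)
  vals <- vapply(ratios, function(r) channel_value_model(r, 1, 0.9, 0.1, 1, 1),
                 numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(vals[1], 0.1, tolerance = 1e-3)
  expect_equal(vals[30], 0.9, tolerance = 1e-3)
  expect_error(channel_value_model(0, 0, 0.5, 0.5, 1, 1), "undefined")
})

test_that("NIR-red ratios are per channel, with defined edge cases", {
  g <- seq(400, 1000, by = 10)
  n <- length(g)
  sens <- matrix(0.2, n, 3)
  s <- sensitivity_set(g, sens)
  r <- nir_red_ratio(s, band_window(600, 700), band_window(800, 900))
  expect_equal(unname(r), c(1, 1, 1))
  sens2 <- sens; sens2[g >= 800 & g < 900, ] <- 0
  expect_equal(unname(nir_red_ratio(sensitivity_set(g, sens2),
                                    band_window(600, 700), band_window(800, 900))),
               c(0, 0, 0))
  # the two-band-pass system records purer NIR in its blue channel than the
  # long-pass system does
  lp <- ncam_camera("ncam_lp"); tp <- ncam_camera("ncam_tp")
  rlp <- nir_red_ratio(lp$eff_sens, lp$windows$red, lp$windows$nir)
  rtp <- nir_red_ratio(tp$eff_sens, tp$windows$red, tp$windows$nir)
  expect_gt(rtp["B"], rlp["B"])
  # and the blue channel is always the purest NIR channel
  expect_true(all(rlp["B"] > rlp[c("R", "G")]))
  expect_true(all(rtp["B"] > rtp[c("R", "G")]))
})

test_that("sensitivity and filter curves round-trip through delimited text", {
  g <- default_grid()
  tr <- make_filter(filter_spec("long_pass"), g)
  path <- file.path(tempdir(), "lp_curve.tsv")
  write_curve(g, tr, path)
  back <- read_curve(path)
  expect_equal(back$wavelength, g)
  expect_equal(back$value, tr, tolerance = 1e-12)
  unlink(path)
})
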