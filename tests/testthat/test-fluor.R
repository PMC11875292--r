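ref05 <- optical_properties(0.5, 10)

test_that("X_1D is exactly 1 under calibration-condition optics", {
  expect_equal(correction_factor(0.5, 10, 0.5, 10, ref05, ref05), 1)
  m <- matrix(0.5, 3, 3)
  s <- matrix(10, 3, 3)
  expect_equal(correction_factor(m, s, m, s, ref05, ref05), matrix(1, 3, 3))
})

test_that("X_1D matches the independently evaluated pathlength golden value", {
  # frozen from a separate analytic evaluation of
  # L = 1 / (mueff_ex + mueff_em), normalised to the reference condition
  expect_equal(correction_factor(1.0, 20, 0.5, 15, ref05, ref05),
               0.622086730402, tolerance = 1e-10)
})

test_that("more absorption strictly shortens the effective pathlength", {
  x1 <- correction_factor(0.5, 20, 0.5, 20, ref05, ref05)
  x2 <- correction_factor(1.0, 20, 1.0, 20, ref05, ref05)
  expect_lt(x2, x1)
  # monotone along a mua sequence at both wavelengths
  mua_seq <- seq(0.2, 3, length.out = 10)
  xs <- correction_factor(mua_seq, 20, mua_seq, 20, ref05, ref05)
  expect_true(all(diff(xs) < 0))
})

test_that("unconverged or invalid pixels are masked in X_1D", {
  m <- matrix(c(0.5, NA, -1, 0.5), 2, 2)
  x <- correction_factor(m, matrix(10, 2, 2), matrix(0.5, 2, 2),
                         matrix(10, 2, 2), ref05, ref05)
  expect_true(is.na(x[2, 1]) && is.na(x[1, 2]))
  expect_false(is.na(x[1, 1]))
})

test_that("fluorescence correction is the dark-subtracted ratio by definition", {
  f <- matrix(1000, 4, 4); dark <- matrix(100, 4, 4)
  expect_equal(correct_fluorescence(f, dark, matrix(1, 4, 4)), f - dark)
  expect_equal(correct_fluorescence(dark, dark, matrix(1, 4, 4)), matrix(0, 4, 4))
  expect_equal(correct_fluorescence(f, dark, matrix(0.9, 4, 4)),
               matrix(900 / 0.9, 4, 4))
  expect_error(correct_fluorescence(f, matrix(0, 2, 2)), "shape")
})

test_that("autofluorescence subtraction isolates the known contribution", {
  f <- matrix(200, 6, 6)
  out0 <- subtract_autofluorescence(f, 0)
  expect_equal(out0$f_signal, f)
  expect_equal(out0$autofluorescence_fraction, 0)

  out1 <- subtract_autofluorescence(f, f)
  expect_equal(out1$f_signal, matrix(0, 6, 6))
  expect_equal(out1$autofluorescence_fraction, 1)
  expect_warning(subtract_autofluorescence(f, f * 1.1), "50%")

  set.seed(41)
  signal <- matrix(runif(36, 50, 150), 6, 6)
  bg <- matrix(runif(36, 1, 20), 6, 6)
  out <- subtract_autofluorescence(signal + bg, bg)
  expect_equal(out$f_signal, signal, tolerance = 1e-10)
})

test_that("calibration line is recovered exactly from linear responses", {
  conc <- c(2, 4, 6, 8)
  cal <- fit_fluor_calibration(conc, 120 * conc + 7)
  expect_equal(cal$slope, 120)
  expect_equal(cal$intercept, 7)
  expect_equal(cal$r_squared, 1)
  # two points: line passes through both exactly
  cal2 <- fit_fluor_calibration(c(2, 8), c(100, 400))
  expect_equal(predict(cal2, c(2, 8)), c(100, 400))
  expect_error(fit_fluor_calibration(c(4, 4, 4), c(1, 2, 3)), "distinct")
})

test_that("noisy calibration slope lies within 3 standard errors of truth", {
  set.seed(42)
  conc <- rep(c(2, 4, 6, 8), each = 10)
  slope_t <- 120
  resp <- slope_t * conc
  noisy <- resp * (1 + rnorm(length(resp), 0, 0.01))
  cal <- fit_fluor_calibration(conc, noisy)
  # closed-form OLS slope variance: sigma^2 / sum((x - xbar)^2)
  sigma <- 0.01 * mean(resp)
  se <- sigma / sqrt(sum((conc - mean(conc))^2))
  expect_lt(abs(cal$slope - slope_t), 3 * se)
})

test_that("concentration conversion inverts the calibration line and clamps at 0", {
  cal <- fit_fluor_calibration(c(2, 4, 6, 8), 120 * c(2, 4, 6, 8) + 7)
  expect_equal(to_concentration(matrix(7, 2, 2), cal), matrix(0, 2, 2))
  expect_equal(to_concentration(matrix(120 * 5 + 7, 2, 2), cal),
               matrix(5, 2, 2), tolerance = 1e-12)
  expect_message(to_concentration(matrix(0, 2, 2), cal), "clamped")
  bad <- cal; bad$slope <- -1
  expect_error(to_concentration(matrix(1, 2, 2), bad), "slope")
})

test_that("full synthetic fluorescence chain recovers a varied concentration map", {
  set.seed(43)
  shape <- c(24, 24)
  conc_t <- matrix(runif(prod(shape), 1, 10), shape[1], shape[2])
  mua <- array(runif(prod(shape) * 2, 0.5, 1.5), c(shape, 2))
  musp <- array(runif(prod(shape) * 2, 10, 30), c(shape, 2))
  scene <- synthetic_scene(mua, musp, c(490, 590), fluor = conc_t)
  cal_truth <- list(slope = 1500, intercept = 40)
  fr <- render_fluorescence_frame(scene, 490, 590, cal_truth, ref05, ref05,
                                  noise = noise_model(multiplicative_sigma = 0.01,
                                                      seed = 7),
                                  dark_level = 100)
  x1d <- correction_factor(mua[, , 1], musp[, , 1], mua[, , 2], musp[, , 2],
                           ref05, ref05)
  fcorr <- correct_fluorescence(fr$f_raw, fr$dark, x1d)
  cal <- fit_fluor_calibration(c(2, 4, 6, 8), 1500 * c(2, 4, 6, 8) + 40)
  conc <- to_concentration(fcorr, cal)
  expect_lt(max(abs(conc - conc_t) / conc_t), 0.10)
})
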