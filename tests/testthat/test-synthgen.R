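test_that("noiseless rendering makes demodulated AC equal gain times Rd", {
  fx <- frequency_set(seq(0, 2.5, length.out = 5))
  scene <- synthetic_scene(matrix(0.7, 16, 16), matrix(14, 16, 16), 660)
  stk <- render_reflectance_stack(scene, fx, gain = 1000)
  d <- demodulate(stk)
  for (f in seq_along(fx)) {
    truth <- 1000 * forward_reflectance(0.7, 14, fx[f])
    expect_equal(as.vector(d$mac[, , f, 1]), rep(truth, 256), tolerance = 1e-10)
  }
})

test_that("round trip through demodulate, calibrate and fit recovers all 9 grid points", {
  suite <- make_phantom_suite(shape = c(12, 12))
  props <- list("660" = optical_properties(0.5, 10))
  ref <- reference_phantom(demodulate(suite[[1]]$stack), props)
  for (el in suite) {
    rd <- calibrate_reflectance(demodulate(el$stack), ref)
    fit <- fit_optical_properties(rd)
    expect_lt(max(abs(fit$mua / el$truth$mua - 1)), 1e-4)
    expect_lt(max(abs(fit$musp / el$truth$musp - 1)), 1e-4)
  }
})

test_that("multiplicative noise propagates at the declared level into AC maps", {
  fx <- frequency_set(c(0, 1))
  scene <- synthetic_scene(matrix(0.8, 64, 64), matrix(15, 64, 64), 660)
  stk <- render_reflectance_stack(scene, fx,
                                  noise = noise_model(multiplicative_sigma = 0.01,
                                                      seed = 61))
  suppressWarnings(d <- demodulate(stk))
  mac <- d$mac[, , 2, 1]
  # AC amplitude is a quadrature combination of three noisy frames; its
  # relative spread tracks the per-frame 1% within a modest factor
  rel_sd <- sd(mac) / mean(mac)
  expect_gt(rel_sd, 0.01 * 0.5)
  expect_lt(rel_sd, 0.01 * 2.5)
})

test_that("rendering is seed-deterministic", {
  fx <- frequency_set(c(0, 1))
  scene <- synthetic_scene(matrix(0.8, 8, 8), matrix(15, 8, 8), 660)
  nm <- noise_model(multiplicative_sigma = 0.02, seed = 62)
  s1 <- render_reflectance_stack(scene, fx, noise = nm)
  s2 <- render_reflectance_stack(scene, fx, noise = nm)
  expect_identical(s1$images, s2$images)
  s3 <- render_reflectance_stack(scene, fx,
                                 noise = noise_model(multiplicative_sigma = 0.02,
                                                     seed = 63))
  expect_false(identical(s1$images, s3$images))
})

test_that("frequencies beyond the pixel Nyquist limit are rejected", {
  scene <- synthetic_scene(matrix(0.8, 8, 8), matrix(15, 8, 8), 660)
  expect_error(render_reflectance_stack(scene, frequency_set(c(0, 25)),
                                        pixels_per_cm = 40),
               "Nyquist")
})

test_that("fluorescence frames invert the correction chain by construction", {
  ref <- optical_properties(0.5, 10)
  shape <- c(10, 10)
  # zero concentration, zero background: frame equals the dark level
  scene0 <- synthetic_scene(array(0.5, c(shape, 2)), array(10, c(shape, 2)),
                            c(490, 590), fluor = matrix(0, 10, 10))
  fr0 <- render_fluorescence_frame(scene0, 490, 590,
                                   list(slope = 1000, intercept = 0),
                                   ref, ref, dark_level = 80)
  expect_equal(fr0$f_raw, matrix(80, 10, 10))

  # uniform 5 ug/mL under calibration optics: exact noiseless recovery
  scene5 <- synthetic_scene(array(0.5, c(shape, 2)), array(10, c(shape, 2)),
                            c(490, 590), fluor = matrix(5, 10, 10))
  fr5 <- render_fluorescence_frame(scene5, 490, 590,
                                   list(slope = 1000, intercept = 0),
                                   ref, ref, dark_level = 80)
  fcorr <- correct_fluorescence(fr5$f_raw, fr5$dark, 1)
  cal <- fit_fluor_calibration(c(2, 4), 1000 * c(2, 4))
  expect_equal(to_concentration(fcorr, cal), matrix(5, 10, 10),
               tolerance = 1e-12)
})

test_that("a high-absorption tumor can invert raw contrast but not concentration contrast", {
  ref <- optical_properties(0.5, 10)
  shape <- c(20, 20)
  mua <- matrix(0.5, 20, 20); musp <- matrix(10, 20, 20)
  conc <- matrix(0.183, 20, 20)
  disc <- (row(mua) - 10)^2 + (col(mua) - 10)^2 <= 25
  mua[disc] <- 1.5; musp[disc] <- 30; conc[disc] <- 0.24
  scene <- synthetic_scene(array(rep(mua, 2), c(shape, 2)),
                           array(rep(musp, 2), c(shape, 2)),
                           c(490, 590), fluor = conc)
  fr <- render_fluorescence_frame(scene, 490, 590,
                                  list(slope = 1e4, intercept = 0), ref, ref)
  # the X_1D penalty of the dark tumor exceeds its 1.31-fold concentration
  # contrast, so raw fluorescence contrast is inverted
  expect_lt(mean(fr$f_raw[disc]), mean(fr$f_raw[!disc]))
  x1d <- correction_factor(mua, musp, mua, musp, ref, ref)
  conc_rec <- correct_fluorescence(fr$f_raw, 0, x1d) / 1e4
  expect_gt(mean(conc_rec[disc]), mean(conc_rec[!disc]))
})

test_that("the fluorophore-titration suite yields the exact calibration line", {
  suite <- make_fluor_calibration_suite(shape = c(8, 8))
  conc <- vapply(suite, `[[`, numeric(1), "concentration")
  expect_equal(conc, c(2, 4, 6, 8))
  fcorr <- vapply(suite, function(el)
    mean(correct_fluorescence(el$f_raw, el$dark, 1)), numeric(1))
  cal <- fit_fluor_calibration(conc, fcorr)
  expect_equal(cal$slope, 1200, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
})

test_that("scene construction validates shapes and positivity", {
  expect_error(synthetic_scene(matrix(0, 4, 4), matrix(10, 4, 4), 660),
               "positive")
  expect_error(synthetic_scene(matrix(1, 4, 4), matrix(10, 5, 5), 660),
               "differ|shape")
  expect_error(synthetic_scene(matrix(1, 4, 4), matrix(10, 4, 4), 660,
                               fluor = matrix(-1, 4, 4)), ">= 0")
})
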