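fx5 <- seq(0, 2.5, length.out = 5)
fx22 <- seq(0, 3.1764, length.out = 22)

test_that("noiseless curves round-trip through the fit to high accuracy", {
  rd <- make_rd_object(matrix(0.8, 2, 2), matrix(15, 2, 2), fx5)
  fit <- fit_optical_properties(rd)
  expect_lt(max(abs(fit$mua / 0.8 - 1)), 1e-4)
  expect_lt(max(abs(fit$musp / 15 - 1)), 1e-4)
  expect_true(all(fit$converged))
  expect_lt(max(fit$residual_norm), 1e-8)
})

test_that("the fit minimizer agrees with a dense grid-search oracle", {
  set.seed(31)
  for (i in 1:10) {
    mua <- runif(1, 0.3, 2); musp <- runif(1, 8, 40)
    curve <- forward_reflectance(mua, musp, fx5) * (1 + rnorm(5, 0, 0.01))
    rd <- structure(list(rd = array(curve, c(1, 1, 5, 1)),
                         frequencies = frequency_set(fx5), wavelengths = 660,
                         n_masked = 0L), class = "calibrated_reflectance")
    fit <- fit_optical_properties(rd)
    oracle <- grid_search_op(curve, fx5)
    expect_lt(abs(fit$mua[1, 1, 1] - oracle$mua), oracle$cell[1] * 1.0 + 1e-12)
    expect_lt(abs(fit$musp[1, 1, 1] - oracle$musp), oracle$cell[2] * 1.0 + 1e-12)
  }
})

test_that("parameter recovery at 1% noise stays within 5% median error (22 frequencies)", {
  set.seed(32)
  npair <- 50
  mua_t <- runif(npair, 0.5, 1.5)
  musp_t <- runif(npair, 10, 30)
  rd <- array(NA_real_, c(npair, 1, 22, 1))
  for (f in seq_along(fx22))
    rd[, 1, f, 1] <- forward_reflectance(mua_t, musp_t, fx22[f]) *
      (1 + rnorm(npair, 0, 0.01))
  obj <- structure(list(rd = rd, frequencies = frequency_set(fx22),
                        wavelengths = 660, n_masked = 0L),
                   class = "calibrated_reflectance")
  fit <- fit_optical_properties(obj)
  ape_mua <- abs(fit$mua[, 1, 1] - mua_t) / mua_t * 100
  ape_musp <- abs(fit$musp[, 1, 1] - musp_t) / musp_t * 100
  expect_lt(median(ape_mua), 5)
  expect_lt(median(ape_musp), 5)
})

test_that("recovery succeeds for both the 5- and 22-frequency configurations", {
  set.seed(33)
  for (fx in list(fx5, fx22)) {
    mua_t <- c(0.5, 1.0, 1.5); musp_t <- c(10, 20, 30)
    rd <- array(NA_real_, c(3, 1, length(fx), 1))
    for (f in seq_along(fx))
      rd[, 1, f, 1] <- forward_reflectance(mua_t, musp_t, fx[f]) *
        (1 + rnorm(3, 0, 0.01))
    obj <- structure(list(rd = rd, frequencies = frequency_set(fx),
                          wavelengths = 660, n_masked = 0L),
                     class = "calibrated_reflectance")
    fit <- fit_optical_properties(obj)
    expect_true(all(abs(fit$mua[, 1, 1] - mua_t) / mua_t < 0.10))
    expect_true(all(abs(fit$musp[, 1, 1] - musp_t) / musp_t < 0.10))
  }
})

test_that("identical inputs produce bit-identical maps", {
  set.seed(34)
  rd <- make_rd_object(matrix(runif(16, 0.5, 1.5), 4, 4),
                       matrix(runif(16, 10, 30), 4, 4), fx5,
                       noise_sigma = 0.01)
  f1 <- fit_optical_properties(rd)
  f2 <- fit_optical_properties(rd)
  expect_identical(f1$mua, f2$mua)
  expect_identical(f1$musp, f2$musp)
})

test_that("pixels with fewer than two usable frequencies are unconverged NAs", {
  rd <- make_rd_object(matrix(0.8, 3, 3), matrix(15, 3, 3), fx5)
  rd$rd[1, 1, 2:5, 1] <- NA  # one frequency left
  rd$rd[2, 2, , 1] <- NA     # nothing left
  fit <- fit_optical_properties(rd)
  expect_true(is.na(fit$mua[1, 1, 1]) && is.na(fit$mua[2, 2, 1]))
  expect_false(fit$converged[1, 1, 1] || fit$converged[2, 2, 1])
  expect_false(anyNA(fit$mua[3, , 1]))
})

test_that("the vectorised optimiser matches per-pixel L-BFGS-B", {
  set.seed(35)
  for (i in 1:5) {
    mua <- runif(1, 0.4, 1.6); musp <- runif(1, 9, 32)
    curve <- forward_reflectance(mua, musp, fx5) * (1 + rnorm(5, 0, 0.005))
    rd <- structure(list(rd = array(curve, c(1, 1, 5, 1)),
                         frequencies = frequency_set(fx5), wavelengths = 660,
                         n_masked = 0L), class = "calibrated_reflectance")
    fit <- fit_optical_properties(rd)
    ob <- function(p) sum((forward_reflectance(p[1], p[2], fx5) - curve)^2)
    ref <- optim(c(0.5, 15), ob, method = "L-BFGS-B",
                 lower = c(1e-3, 1), upper = c(5, 100),
                 control = list(factr = 10))
    expect_equal(fit$mua[1, 1, 1], ref$par[1], tolerance = 1e-3)
    expect_equal(fit$musp[1, 1, 1], ref$par[2], tolerance = 1e-3)
  }
})

test_that("pixel binning mean-pools reflectance and reduces map size", {
  rd <- make_rd_object(matrix(0.8, 8, 8), matrix(15, 8, 8), fx5)
  fit <- fit_optical_properties(rd, binning = 4)
  expect_equal(dim(fit$mua)[1:2], c(2, 2))
  expect_lt(max(abs(fit$mua / 0.8 - 1)), 1e-4)
  # binning a checkerboard averages the two reflectance levels
  m <- matrix(c(1, 3), 2, 2)
  a <- array(m, c(2, 2, 1, 1))
  expect_equal(as.vector(sfdiq:::.bin_array(a, 2)), 2)
})

test_that("fit object methods expose coefficients, predictions and residuals", {
  rd <- make_rd_object(matrix(0.8, 2, 2), matrix(15, 2, 2), fx5)
  fit <- fit_optical_properties(rd)
  co <- coef(fit)
  expect_named(co, c("mua", "musp"))
  pr <- predict(fit)
  expect_equal(dim(pr), c(2, 2, 5, 1))
  expect_equal(pr[1, 1, , 1], forward_reflectance(0.8, 15, fx5), tolerance = 1e-4)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  s <- summary(fit)
  expect_s3_class(s, "summary.sfdi_fit")
  expect_equal(unname(s$table[1, "convergence_rate"]), 1)
  sim <- simulate(fit, nsim = 2, seed = 1, sigma = 0.01)
  expect_length(sim, 2)
  expect_false(identical(sim[[1]], sim[[2]]))
})
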