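#' Attenuation correction factor X_1D(ex, em)
#'
#' Fluorescence measured at the surface of a turbid medium is attenuated
#' twice: the excitation light decays on the way in and the emitted light is
#' attenuated on the way out.  Modelling both legs as exponential decay with
#' the effective attenuation coefficient mueff = sqrt(3 mua (mua + musp)),
#' the detected signal from a uniformly fluorescent medium is proportional
#' to the 1D effective path length
#' \deqn{L = \int_0^\infty e^{-(\mu_{eff,ex} + \mu_{eff,em}) z}\, dz
#'       = \frac{1}{\mu_{eff,ex} + \mu_{eff,em}}}
#' The correction factor is this path length normalised to the calibration
#' phantom's optical properties,
#' \deqn{X_{1D} = L(\mu_a, \mu_s')\ /\ L(ref)}
#' so that X_1D = 1 exactly under the calibration conditions, and absolute
#' scale lives entirely in the fluorescence calibration curve.  Corrected
#' fluorescence is \code{f_raw / x1d}.
#'
#' All map arguments are vectorised; unconverged (NA) pixels stay NA.
#'
#' @param mua_ex,musp_ex Absorption/reduced-scattering maps (cm^-1) at the
#'   excitation wavelength (matrices or vectors).
#' @param mua_em,musp_em Same at the emission wavelength.
#' @param ref_ex,ref_em \code{\link{optical_properties}} of the calibration
#'   phantom at the excitation and emission wavelengths.
#' @return Map of X_1D values, dimensionless, > 0; NA where inputs are NA or
#'   non-positive.
#' @examples
#' ref <- optical_properties(0.5, 10)
#' correction_factor(0.5, 10, 0.5, 10, ref, ref)  # exactly 1
#' @export
correction_factor <- function(mua_ex, musp_ex, mua_em, musp_em, ref_ex, ref_em) {
  stopifnot(inherits(ref_ex, "optical_properties"),
            inherits(ref_em, "optical_properties"))
  mueff <- function(mua, musp) sqrt(3 * mua * (mua + musp))
  denom_ref <- mueff(ref_ex$mua, ref_ex$musp) + mueff(ref_em$mua, ref_em$musp)
  bad <- !is.finite(mua_ex) | !is.finite(musp_ex) |
         !is.finite(mua_em) | !is.finite(musp_em) |
         mua_ex <= 0 | musp_ex <= 0 | mua_em <= 0 | musp_em <= 0
  mua_ex[bad] <- NA_real_   # keep sqrt off negative arguments
  mua_em[bad] <- NA_real_
  denom_ref / (mueff(mua_ex, musp_ex) + mueff(mua_em, musp_em))
}

#' X_1D map from a fitted optical-property map
#'
#' Convenience wrapper extracting the excitation- and emission-wavelength
#' slices of an \code{\link{fit_optical_properties}} result.
#'
#' @param fit An \code{sfdi_fit} whose wavelengths include the excitation and
#'   emission bands.
#' @param ex_nm,em_nm Excitation and emission wavelengths in nm (must match
#'   entries of \code{fit$wavelengths}).
#' @param ref_ex,ref_em Calibration-phantom \code{\link{optical_properties}}
#'   at those wavelengths.
#' @return X_1D matrix (rows, cols).
#' @export
correction_factor_map <- function(fit, ex_nm, em_nm, ref_ex, ref_em) {
  stopifnot(inherits(fit, "sfdi_fit"))
  ie <- match(ex_nm, fit$wavelengths)
  im <- match(em_nm, fit$wavelengths)
  if (is.na(ie) || is.na(im))
    stop("fit does not contain the requested excitation/emission wavelengths")
  correction_factor(fit$mua[, , ie], fit$musp[, , ie],
                    fit$mua[, , im], fit$musp[, , im], ref_ex, ref_em)
}

#' Correct raw fluorescence for tissue attenuation
#'
#' \code{f_corr = max(f_raw - dark, 0) / x1d}, masked (NA) wherever the
#' correction factor is undefined.
#'
#' @param f_raw Raw fluorescence frame (matrix, camera units).
#' @param dark Dark frame (matrix, same shape) or a scalar; 0 to skip.
#' @param x1d Correction-factor map from \code{\link{correction_factor}},
#'   same shape (or scalar).
#' @return Corrected fluorescence matrix, camera units.
#' @export
correct_fluorescence <- function(f_raw, dark = 0, x1d = 1) {
  if (length(dark) > 1L && !all(dim(dark) == dim(f_raw)))
    stop("'dark' shape does not match 'f_raw'")
  if (length(x1d) > 1L && !all(dim(x1d) == dim(f_raw)))
    stop("'x1d' shape does not match 'f_raw'")
  pmax(f_raw - dark, 0) / x1d
}

#' Subtract tissue autofluorescence from corrected fluorescence
#'
#' The background (a pre-injection corrected-fluorescence map acquired under
#' identical settings, or a scalar ROI mean) is subtracted and the result
#' clamped at zero.  The returned diagnostic
#' \code{autofluorescence_fraction} is the ratio of mean background to mean
#' total signal over the ROI (whole frame if no ROI given).
#'
#' @param f_corr Corrected fluorescence map.
#' @param background Pre-injection corrected fluorescence: matrix (same
#'   shape) or scalar.
#' @param roi Optional \code{\link{roi_polygon}} or logical mask over which
#'   the diagnostic fraction is computed.
#' @return List with \code{f_signal} (map), \code{autofluorescence_fraction}
#'   (scalar) and \code{background_dominant} (TRUE if background exceeds the
#'   signal over more than half the ROI — a warning sign).
#' @export
subtract_autofluorescence <- function(f_corr, background, roi = NULL) {
  bg <- if (length(background) == 1L) {
    matrix(background, nrow(f_corr), ncol(f_corr))
  } else {
    if (!all(dim(background) == dim(f_corr)))
      stop("'background' shape does not match 'f_corr'")
    background
  }
  f_signal <- pmax(f_corr - bg, 0)
  sel <- if (is.null(roi)) {
    !is.na(f_corr)
  } else {
    as_roi_mask(roi, dim(f_corr)) & !is.na(f_corr)
  }
  mtot <- mean(f_corr[sel])
  frac <- if (mtot > 0) mean(bg[sel]) / mtot else NA_real_
  dominant <- mean(bg[sel] > f_corr[sel]) > 0.5
  if (isTRUE(dominant))
    warning("background exceeds the signal over more than 50% of the ROI")
  list(f_signal = f_signal, autofluorescence_fraction = frac,
       background_dominant = dominant)
}

#' Fit a fluorescence concentration calibration curve
#'
#' Ordinary least-squares line through corrected-fluorescence measurements of
#' phantoms at known fluorophore concentrations:
#' \code{f_corr = slope * C + intercept}.  Inverting this line converts
#' corrected fluorescence to absolute concentration
#' (\code{\link{to_concentration}}).
#'
#' @param concentrations Known concentrations, ug/mL (>= 2 distinct values).
#' @param fcorr Matching corrected-fluorescence values, camera units.
#' @return Object of class \code{"fluor_calibration"} with \code{slope},
#'   \code{intercept}, \code{r_squared} and the underlying \code{lm} fit.
#'   A warning is issued when r^2 < 0.98 or the slope is non-positive.
#' @examples
#' cal <- fit_fluor_calibration(c(2, 4, 6, 8), c(2, 4, 6, 8) * 120 + 5)
#' coef(cal)
#' @export
fit_fluor_calibration <- function(concentrations, fcorr) {
  if (length(concentrations) != length(fcorr))
    stop("'concentrations' and 'fcorr' lengths differ")
  if (length(unique(concentrations)) < 2L)
    stop("at least 2 distinct concentrations are required")
  fit <- stats::lm(fcorr ~ concentrations)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # suppressed: summary.lm warns on exactly linear data, which is the
  # expected case for noiseless synthetic calibrations
  r2 <- if (length(concentrations) > 2L)
    suppressWarnings(summary(fit)$r.squared) else 1
  if (slope <= 0) warning("calibration slope is non-positive")
  if (r2 < 0.98) warning(sprintf("calibration r^2 = %.3f is below 0.98", r2))
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 concentrations = concentrations, fcorr = fcorr, lm = fit),
            class = "fluor_calibration")
}

#' @export
print.fluor_calibration <- function(x, ...) {
  cat(sprintf("fluorescence calibration: f_corr = %.6g * C + %.6g (r^2 = %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, length(x$concentrations)))
  invisible(x)
}

#' @export
coef.fluor_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.fluor_calibration <- function(object, concentrations, ...) {
  object$slope * concentrations + object$intercept
}

#' Convert corrected fluorescence to absolute concentration
#'
#' Inverts the calibration line: \code{C = (f_signal - intercept) / slope},
#' clamped at zero (negative concentrations are unphysical; the clamp count
#' is reported via message).
#'
#' @param f_signal Background-subtracted corrected-fluorescence map.
#' @param cal A \code{\link{fit_fluor_calibration}} object.
#' @return Concentration map in ug/mL.
#' @export
to_concentration <- function(f_signal, cal) {
  if (!inherits(cal, "fluor_calibration")) stop("'cal' must be a fluor_calibration")
  if (cal$slope <= 0) stop("calibration slope must be positive")
  conc <- (f_signal - cal$intercept) / cal$slope
  nneg <- sum(conc < 0, na.rm = TRUE)
  if (nneg > 0)
    message(sprintf("%d negative concentration value(s) clamped to 0", nneg))
  pmax(conc, 0)
}
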