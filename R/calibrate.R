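#' Reference phantom measurement with known optical properties
#'
#' Couples a demodulated acquisition of a homogeneous calibration phantom
#' with its known per-wavelength optical properties.  The phantom converts
#' raw demodulated camera amplitudes into absolute diffuse reflectance.
#'
#' @param demod A \code{\link{demodulate}}d set measured on the phantom under
#'   the same acquisition settings as the sample.
#' @param props_by_wavelength Named list mapping wavelength (nm, as character
#'   or numeric names) to \code{\link{optical_properties}}; must cover every
#'   wavelength in \code{demod}.
#' @return Object of class \code{"reference_phantom"}.
#' @export
reference_phantom <- function(demod, props_by_wavelength) {
  if (!inherits(demod, "demodulated_set")) stop("'demod' must be a demodulated_set")
  keys <- suppressWarnings(as.numeric(names(props_by_wavelength)))
  if (anyNA(keys)) stop("'props_by_wavelength' must have numeric wavelength names (nm)")
  idx <- match(demod$wavelengths, keys)
  if (anyNA(idx))
    stop("reference phantom properties missing for wavelength(s): ",
         paste(demod$wavelengths[is.na(idx)], collapse = ", "), " nm")
  props <- props_by_wavelength[idx]
  ok <- vapply(props, inherits, logical(1), "optical_properties")
  if (!all(ok)) stop("each element of 'props_by_wavelength' must be optical_properties()")
  structure(list(demod = demod, props = props), class = "reference_phantom")
}

#' Calibrate demodulated amplitudes to absolute diffuse reflectance
#'
#' Ratio calibration against a reference phantom of known optical
#' properties: per pixel and (fx, lambda),
#' \deqn{R_{d,sample} = \frac{M_{AC,sample}}{M_{AC,ref}}
#'   \cdot R_{d,model}(f_x;\ \mu_a^{ref}, \mu_s'^{ref})}
#' where the model prediction comes from \code{\link{forward_reflectance}}.
#' This cancels the instrument throughput and the illumination profile.
#'
#' Pixels where the reference amplitude is zero, either image is saturated,
#' or the resulting reflectance exceeds 1 (non-physical) are masked (NA),
#' never clipped.
#'
#' @param sample Demodulated set of the sample.
#' @param ref A \code{\link{reference_phantom}} on the same frequency and
#'   wavelength grids and image shape.
#' @param ref_mode \code{"pixel"} (default) uses the per-pixel phantom
#'   amplitude and so corrects illumination non-uniformity;
#'   \code{"mean"} averages the phantom over its field of view first.
#' @return Object of class \code{"calibrated_reflectance"}: list with
#'   \code{rd} (rows, cols, frequency, wavelength; NA where masked),
#'   \code{frequencies}, \code{wavelengths}, \code{n_masked}.
#' @export
calibrate_reflectance <- function(sample, ref, ref_mode = c("pixel", "mean")) {
  ref_mode <- match.arg(ref_mode)
  if (!inherits(sample, "demodulated_set")) stop("'sample' must be a demodulated_set")
  if (!inherits(ref, "reference_phantom")) stop("'ref' must be a reference_phantom")
  rdem <- ref$demod
  if (!isTRUE(all.equal(as.numeric(sample$frequencies), as.numeric(rdem$frequencies))))
    stop("sample and reference frequency grids differ")
  if (!identical(sample$wavelengths, rdem$wavelengths))
    stop("sample and reference wavelength grids differ")
  ds <- dim(sample$mac)
  if (!all(ds == dim(rdem$mac)))
    stop("sample and reference image shapes differ")
  nr <- ds[1]; nc <- ds[2]; nf <- ds[3]; nw <- ds[4]

  rd <- array(NA_real_, ds)
  nzero <- 0L
  for (w in seq_len(nw)) {
    pr <- ref$props[[w]]
    for (f in seq_len(nf)) {
      rd_model <- forward_reflectance(pr$mua, pr$musp, sample$frequencies[f], pr$n)
      mref <- rdem$mac[, , f, w]
      if (ref_mode == "mean") mref[] <- mean(mref[!rdem$saturation_mask])
      bad <- mref <= 0
      nzero <- nzero + sum(bad)
      mref[bad] <- NA_real_
      rd[, , f, w] <- sample$mac[, , f, w] / mref * rd_model
    }
  }
  if (nzero > 0)
    warning(sprintf("%d pixel-frame(s) masked: zero reference amplitude", nzero))

  # propagate saturation masks from both measurements
  sat <- sample$saturation_mask | rdem$saturation_mask
  if (any(sat)) rd[rep(sat, times = nf * nw)] <- NA_real_

  over <- !is.na(rd) & rd > 1
  if (any(over)) {
    warning(sprintf("%d pixel-frame(s) masked: Rd > 1 is non-physical", sum(over)))
    rd[over] <- NA_real_
  }

  structure(list(rd = rd, frequencies = sample$frequencies,
                 wavelengths = sample$wavelengths,
                 n_masked = sum(is.na(rd))),
            class = "calibrated_reflectance")
}

#' @export
print.calibrated_reflectance <- function(x, ...) {
  d <- dim(x$rd)
  cat(sprintf("calibrated reflectance: %d x %d px, %d frequencies, %d wavelength(s); %d masked value(s)\n",
              d[1], d[2], d[3], d[4], x$n_masked))
  invisible(x)
}
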