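#' Raw structured-illumination acquisition stack
#'
#' Container for one SFDI acquisition: three phase-shifted intensity images
#' (nominal phases 0, 2pi/3, 4pi/3) per spatial frequency and wavelength,
#' plus optional dark frame and acquisition metadata.
#'
#' @param images 5-D numeric array with dimensions
#'   \code{(rows, cols, phase = 3, frequency, wavelength)}, arbitrary linear
#'   camera units, non-negative.
#' @param frequencies A \code{\link{frequency_set}} (cm^-1) matching dim 4.
#' @param wavelengths Numeric vector of wavelength centers in nm matching
#'   dim 5 (or a list of \code{\link{wavelength_band}}).
#' @param dark Optional dark frame, a \code{rows x cols} matrix in the same
#'   camera units, subtracted before demodulation.
#' @param meta Named list of acquisition metadata (exposure_ms, binning,
#'   pixels_per_cm, timestamps, ...).  \code{pixels_per_cm} declares the
#'   spatial calibration that maps fx in cm^-1 to cycles per pixel.
#' @return An object of class \code{"acquisition_stack"}.
#' @export
acquisition_stack <- function(images, frequencies, wavelengths, dark = NULL,
                              meta = list()) {
  if (!is.array(images) || length(dim(images)) != 5L)
    stop("'images' must be a 5-D array (rows, cols, phase, frequency, wavelength)")
  d <- dim(images)
  if (d[3L] != 3L)
    stop("exactly 3 phase images are required per (frequency, wavelength)")
  if (!inherits(frequencies, "frequency_set")) frequencies <- frequency_set(frequencies)
  if (length(frequencies) != d[4L])
    stop("length(frequencies) must match dim(images)[4]")
  wl <- .wavelength_centers(wavelengths)
  if (length(wl) != d[5L])
    stop("number of wavelengths must match dim(images)[5]")
  if (anyNA(images) || any(images < 0))
    stop("raw intensities must be finite and non-negative")
  if (!is.null(dark)) {
    if (!is.matrix(dark) || !all(dim(dark) == d[1:2]))
      stop("'dark' must be a matrix with the image (rows, cols) shape")
  }
  structure(list(images = images, frequencies = frequencies,
                 wavelengths = wl, dark = dark, meta = meta),
            class = "acquisition_stack")
}

.wavelength_centers <- function(wavelengths) {
  if (is.list(wavelengths))
    wavelengths <- vapply(wavelengths, function(w) {
      if (inherits(w, "wavelength_band")) w$center_nm else as.numeric(w)
    }, numeric(1))
  wl <- as.numeric(wavelengths)
  if (anyNA(wl) || any(wl <= 0)) stop("wavelengths must be positive (nm)")
  wl
}

#' @export
print.acquisition_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("SFDI acquisition stack: %d x %d px, 3 phases, %d frequencies (%g-%g cm^-1), %d wavelength(s)\n",
              d[1], d[2], d[4], min(x$frequencies), max(x$frequencies), d[5]))
  cat(sprintf("  dark frame: %s\n", if (is.null(x$dark)) "none" else "present"))
  invisible(x)
}

#' @export
print.demodulated_set <- function(x, ...) {
  d <- dim(x$mac)
  cat(sprintf("demodulated set: %d x %d px, %d frequencies, %d wavelength(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  saturated pixels: %d\n", sum(x$saturation_mask)))
  invisible(x)
}
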