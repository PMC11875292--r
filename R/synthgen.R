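#' Ground-truth scene for synthetic acquisitions
#'
#' Holds the per-pixel, per-wavelength optical properties, fluorophore
#' concentration and autofluorescence level from which synthetic reflectance
#' stacks and fluorescence frames are rendered.
#'
#' @param mua,musp Ground-truth property maps, cm^-1: either a matrix (one
#'   wavelength or shared across all) or an array (rows, cols, n_wavelength).
#' @param wavelengths Wavelength centers in nm.
#' @param fluor Optional fluorophore concentration map, ug/mL (matrix).
#' @param background Autofluorescence level, camera units (matrix or scalar).
#' @param n Refractive index of the medium.
#' @return Object of class \code{"synthetic_scene"}.
#' @export
synthetic_scene <- function(mua, musp, wavelengths, fluor = NULL,
                            background = 0, n = 1.4) {
  wl <- .wavelength_centers(wavelengths)
  expand <- function(x, nm) {
    if (is.matrix(x)) x <- array(rep(x, length(wl)), c(dim(x), length(wl)))
    if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != length(wl))
      stop("'", nm, "' must be a matrix or (rows, cols, n_wavelength) array")
    if (anyNA(x) || any(x <= 0)) stop("'", nm, "' must be positive everywhere")
    x
  }
  mua <- expand(mua, "mua"); musp <- expand(musp, "musp")
  if (!all(dim(mua) == dim(musp))) stop("'mua' and 'musp' shapes differ")
  shape <- dim(mua)[1:2]
  if (!is.null(fluor)) {
    if (!is.matrix(fluor) || !all(dim(fluor) == shape))
      stop("'fluor' must be a matrix matching the scene shape")
    if (anyNA(fluor) || any(fluor < 0)) stop("'fluor' must be >= 0")
  }
  if (length(background) == 1L) background <- matrix(background, shape[1], shape[2])
  if (!all(dim(background) == shape)) stop("'background' shape mismatch")
  structure(list(mua = mua, musp = musp, wavelengths = wl, fluor = fluor,
                 background = background, n = n, shape = shape),
            class = "synthetic_scene")
}

#' Camera noise model for synthetic rendering
#'
#' @param multiplicative_sigma Relative Gaussian noise fraction (shot-noise
#'   proxy), >= 0.
#' @param read_sigma Additive Gaussian read noise, camera units, >= 0.
#' @param full_scale Detector full-scale (clip level), default 65535.
#' @param seed Optional integer seed; rendering with the same seed is
#'   bit-identical.
#' @return Object of class \code{"noise_model"}.
#' @export
noise_model <- function(multiplicative_sigma = 0, read_sigma = 0,
                        full_scale = 65535, seed = NULL) {
  if (multiplicative_sigma < 0 || read_sigma < 0) stop("noise sigmas must be >= 0")
  structure(list(multiplicative_sigma = multiplicative_sigma,
                 read_sigma = read_sigma, full_scale = full_scale, seed = seed),
            class = "noise_model")
}

.apply_noise <- function(img, noise) {
  if (noise$multiplicative_sigma > 0)
    img <- img * (1 + stats::rnorm(length(img), 0, noise$multiplicative_sigma))
  if (noise$read_sigma > 0)
    img <- img + stats::rnorm(length(img), 0, noise$read_sigma)
  pmin(pmax(img, 0), noise$full_scale)
}

#' Render a structured-illumination reflectance stack from a scene
#'
#' For each wavelength, frequency fx and phase phi_k in (0, 2pi/3, 4pi/3),
#' the noiseless frame is
#' \deqn{I_k = dark + G\,[R_d(0) + R_d(f_x)\cos(2\pi f_x x + \phi_k)]}
#' with per-pixel reflectances from \code{\link{forward_reflectance}} and x
#' the position along the column axis in cm (the sinusoid runs along
#' columns; \code{pixels_per_cm} maps cm^-1 to cycles per pixel).  By
#' construction the demodulated AC amplitude equals \code{G * Rd(fx)}
#' exactly in the noiseless case, so the whole downstream chain can be
#' verified against ground truth.  Noise is then applied and the result
#' clipped at the detector full scale.
#'
#' @param scene A \code{\link{synthetic_scene}}.
#' @param frequencies \code{\link{frequency_set}}, cm^-1.
#' @param noise \code{\link{noise_model}}; its seed (if any) is applied
#'   before rendering.
#' @param gain Instrument gain G, camera units per unit reflectance.  The
#'   default maps the peak modulated intensity of an Rd = 0.5 pixel to 60
#'   percent of full scale, leaving headroom so bright phantoms do not clip.
#' @param pixels_per_cm Spatial calibration of the projection (default 40,
#'   i.e. a 3.2 cm field over 128 pixels).
#' @param dark_level Constant dark offset added to every frame; when > 0 a
#'   matching dark frame is attached to the stack.
#' @return An \code{\link{acquisition_stack}}.
#' @export
render_reflectance_stack <- function(scene, frequencies,
                                     noise = noise_model(),
                                     gain = 0.6 * noise$full_scale,
                                     pixels_per_cm = 40,
                                     dark_level = 0) {
  if (!inherits(scene, "synthetic_scene")) stop("'scene' must be a synthetic_scene")
  if (!inherits(frequencies, "frequency_set")) frequencies <- frequency_set(frequencies)
  if (max(frequencies) / pixels_per_cm >= 0.5)
    stop("highest frequency exceeds the Nyquist limit of the pixel grid")
  if (!is.null(noise$seed)) set.seed(noise$seed)

  nr <- scene$shape[1]; nc <- scene$shape[2]
  nf <- length(frequencies); nw <- length(scene$wavelengths)
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  x_cm <- matrix((seq_len(nc) - 1) / pixels_per_cm, nr, nc, byrow = TRUE)

  img <- array(0, c(nr, nc, 3, nf, nw))
  for (w in seq_len(nw)) {
    mua <- scene$mua[, , w]; musp <- scene$musp[, , w]
    rd0 <- forward_reflectance(mua, musp, 0, scene$n)
    for (f in seq_len(nf)) {
      fx <- frequencies[f]
      rdf <- forward_reflectance(mua, musp, fx, scene$n)
      for (p in 1:3) {
        frame <- dark_level + gain * (rd0 + rdf * cos(2 * pi * fx * x_cm + phases[p]))
        img[, , p, f, w] <- .apply_noise(frame, noise)
      }
    }
  }
  acquisition_stack(img, frequencies, scene$wavelengths,
                    dark = if (dark_level > 0) matrix(dark_level, nr, nc) else NULL,
                    meta = list(pixels_per_cm = pixels_per_cm, gain = gain,
                                dark_level = dark_level,
                                full_scale = noise$full_scale, synthetic = TRUE))
}

#' Render a planar raw fluorescence frame from a scene
#'
#' Inverse of the attenuation-correction chain: the raw frame is
#' \deqn{F_{raw} = X_{1D} \cdot (slope \cdot C + intercept) + background
#'   + dark}
#' with X_1D computed from the scene's ground-truth properties at the
#' excitation and emission wavelengths, so that correcting with the true
#' optical properties and inverting the true calibration line recovers the
#' concentration map exactly in the noiseless case.
#'
#' @param scene A \code{\link{synthetic_scene}} with a \code{fluor} map.
#' @param ex_nm,em_nm Excitation and emission wavelengths (must be in
#'   \code{scene$wavelengths}).
#' @param cal_truth List with \code{slope} (> 0) and \code{intercept}: the
#'   ground-truth calibration line, camera units per ug/mL.
#' @param ref_ex,ref_em Calibration-condition \code{\link{optical_properties}}
#'   at the two wavelengths (X_1D is 1 there).
#' @param noise \code{\link{noise_model}}.
#' @param dark_level Constant dark offset (also returned as the dark frame).
#' @return List with \code{f_raw} and \code{dark} matrices.
#' @export
render_fluorescence_frame <- function(scene, ex_nm, em_nm, cal_truth,
                                      ref_ex, ref_em,
                                      noise = noise_model(),
                                      dark_level = 0) {
  if (!inherits(scene, "synthetic_scene")) stop("'scene' must be a synthetic_scene")
  if (is.null(scene$fluor)) stop("scene has no fluorophore map")
  if (!is.list(cal_truth) || is.null(cal_truth$slope) || cal_truth$slope <= 0)
    stop("'cal_truth' must be list(slope > 0, intercept)")
  ie <- match(ex_nm, scene$wavelengths); im <- match(em_nm, scene$wavelengths)
  if (is.na(ie) || is.na(im)) stop("scene lacks the excitation/emission wavelengths")
  if (!is.null(noise$seed)) set.seed(noise$seed)

  x1d <- correction_factor(scene$mua[, , ie], scene$musp[, , ie],
                           scene$mua[, , im], scene$musp[, , im],
                           ref_ex, ref_em)
  intercept <- if (is.null(cal_truth$intercept)) 0 else cal_truth$intercept
  f <- x1d * (cal_truth$slope * scene$fluor + intercept) +
    scene$background + dark_level
  list(f_raw = .apply_noise(f, noise),
       dark = matrix(dark_level, scene$shape[1], scene$shape[2]))
}

#' Synthetic calibration-phantom titration suite
#'
#' One flat homogeneous phantom stack per point of the (mua x musp) grid,
#' each with its ground truth attached.  The first grid point (lowest mua,
#' lowest musp) doubles as the reference phantom for calibration.
#'
#' @param mua_values,musp_values Grid values in cm^-1 (defaults are the
#'   titration range 0.5-1.5 and 10-30 cm^-1).
#' @param frequencies \code{\link{frequency_set}}.
#' @param wavelengths Wavelengths in nm (properties are flat across them).
#' @param shape Image dimensions \code{c(rows, cols)}, default 128 x 128.
#' @param noise \code{\link{noise_model}}; when it carries a seed each
#'   phantom is rendered with a distinct sub-seed derived from it.
#' @param ... Further arguments passed to
#'   \code{\link{render_reflectance_stack}}.
#' @return List of elements \code{list(stack, truth)} where \code{truth}
#'   has \code{mua} and \code{musp}; ordered mua-fastest over the grid.
#' @export
make_phantom_suite <- function(mua_values = c(0.5, 1.0, 1.5),
                               musp_values = c(10, 20, 30),
                               frequencies = frequency_set(seq(0, 2.5, length.out = 5)),
                               wavelengths = 660,
                               shape = c(128, 128),
                               noise = noise_model(), ...) {
  if (length(mua_values) < 1L || length(musp_values) < 1L) stop("empty phantom grid")
  grid <- expand.grid(mua = mua_values, musp = musp_values)
  lapply(seq_len(nrow(grid)), function(i) {
    ni <- noise
    if (!is.null(noise$seed)) ni$seed <- noise$seed + i
    scene <- synthetic_scene(matrix(grid$mua[i], shape[1], shape[2]),
                             matrix(grid$musp[i], shape[1], shape[2]),
                             wavelengths)
    list(stack = render_reflectance_stack(scene, frequencies, noise = ni, ...),
         truth = list(mua = grid$mua[i], musp = grid$musp[i]))
  })
}

#' Synthetic fluorophore-titration calibration suite
#'
#' Uniform-concentration frames at a series of known concentrations under
#' calibration-condition optics (X_1D = 1), from which
#' \code{\link{fit_fluor_calibration}} can recover the calibration line.
#'
#' @param concentrations Concentrations in ug/mL (default 2, 4, 6, 8).
#' @param props \code{\link{optical_properties}} of the calibration phantom
#'   (used at both excitation and emission).
#' @param cal_truth Ground-truth calibration line, list(slope, intercept).
#' @param shape Image dimensions.
#' @param noise \code{\link{noise_model}}.
#' @param ex_nm,em_nm Excitation/emission wavelengths in nm.
#' @return List of \code{list(f_raw, dark, concentration)}.
#' @export
make_fluor_calibration_suite <- function(concentrations = c(2, 4, 6, 8),
                                         props = optical_properties(0.5, 10),
                                         cal_truth = list(slope = 1200, intercept = 0),
                                         shape = c(32, 32),
                                         noise = noise_model(),
                                         ex_nm = 490, em_nm = 590) {
  lapply(seq_along(concentrations), function(i) {
    ni <- noise
    if (!is.null(noise$seed)) ni$seed <- noise$seed + i
    scene <- synthetic_scene(
      mua = array(props$mua, c(shape, 2)),
      musp = array(props$musp, c(shape, 2)),
      wavelengths = c(ex_nm, em_nm),
      fluor = matrix(concentrations[i], shape[1], shape[2]),
      n = props$n)
    fr <- render_fluorescence_frame(scene, ex_nm, em_nm, cal_truth,
                                    props, props, noise = ni)
    c(fr, list(concentration = concentrations[i]))
  })
}
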