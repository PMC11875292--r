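#' Optical properties of a turbid medium
#'
#' Bundle of absorption coefficient, reduced scattering coefficient and
#' refractive index describing a homogeneous turbid medium at one wavelength.
#'
#' @param mua Absorption coefficient in cm^-1 (> 0).
#' @param musp Reduced scattering coefficient in cm^-1 (> 0).
#' @param n Refractive index (>= 1). Defaults to 1.4, typical for soft tissue.
#' @return An object of class \code{"optical_properties"}: a list with
#'   elements \code{mua}, \code{musp}, \code{n} and the derived transport
#'   coefficient \code{mutr = mua + musp}.
#' @examples
#' optical_properties(0.5, 10)
#' @export
optical_properties <- function(mua, musp, n = 1.4) {
  stopifnot(length(mua) == 1L, length(musp) == 1L, length(n) == 1L)
  if (!is.finite(mua) || mua <= 0) stop("'mua' must be a positive finite number (cm^-1)")
  if (!is.finite(musp) || musp <= 0) stop("'musp' must be a positive finite number (cm^-1)")
  if (!is.finite(n) || n < 1) stop("'n' must be a finite refractive index >= 1")
  structure(list(mua = mua, musp = musp, n = n, mutr = mua + musp),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mua = %g cm^-1, musp = %g cm^-1, n = %g\n",
              x$mua, x$musp, x$n))
  invisible(x)
}

#' Validated set of projection spatial frequencies
#'
#' A frequency set is strictly increasing, non-negative, and must contain the
#' planar fx = 0 term (the DC channel used for calibration and for planar
#' fluorescence acquisitions).
#'
#' @param fx Numeric vector of spatial frequencies in cm^-1.
#' @return The sorted numeric vector with class \code{"frequency_set"}.
#' @examples
#' frequency_set(seq(0, 2.5, length.out = 5))
#' @export
frequency_set <- function(fx) {
  fx <- as.numeric(fx)
  if (length(fx) < 1L || anyNA(fx)) stop("frequency set must be non-empty and finite")
  if (any(fx < 0)) stop("spatial frequencies must be non-negative (cm^-1)")
  if (any(diff(fx) <= 0)) stop("frequency set must be strictly increasing")
  if (fx[1L] != 0) stop("frequency set must contain fx = 0 (the planar/DC term)")
  structure(fx, class = "frequency_set")
}

#' Wavelength band with an acquisition role
#'
#' @param center_nm Center wavelength in nm (> 0).
#' @param role One of \code{"reflectance"}, \code{"excitation"},
#'   \code{"emission"}, \code{"treatment"}.
#' @return A list of class \code{"wavelength_band"}.
#' @export
wavelength_band <- function(center_nm,
                            role = c("reflectance", "excitation", "emission", "treatment")) {
  role <- match.arg(role)
  if (!is.finite(center_nm) || center_nm <= 0) stop("'center_nm' must be > 0")
  structure(list(center_nm = center_nm, role = role), class = "wavelength_band")
}

#' Effective boundary reflection coefficient
#'
#' Empirical polynomial approximation of the internal reflection coefficient
#' at a refractive-index-mismatched boundary,
#' Reff = 0.0636 n + 0.668 + 0.710 / n - 1.440 / n^2.
#'
#' @param n Refractive index (>= 1), vectorised.
#' @return Reff, dimensionless.
#' @export
effective_reflection <- function(n) {
  if (any(!is.finite(n)) || any(n < 1)) stop("'n' must be >= 1")
  0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
}

#' Frequency-dependent diffuse reflectance (diffusion approximation)
#'
#' Forward model for the spatially modulated diffuse reflectance of a
#' semi-infinite homogeneous turbid medium.  With transport coefficient
#' mutr = mua + musp, reduced albedo a' = musp / mutr, effective attenuation
#' mueff = sqrt(3 mua mutr) and its modulated extension
#' mueff'(fx) = sqrt(mueff^2 + (2 pi fx)^2), the reflectance is
#' \deqn{R_d(f_x) = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)
#'   (\mu_{eff}'/\mu_{tr} + 3A)}}
#' where the boundary parameter A = (1 - Reff) / (2 (1 + Reff)) encodes the
#' partial-current boundary condition.  The planar fx = 0 case is the same
#' expression with mueff' = mueff, so Rd is continuous at fx = 0.
#'
#' All arguments are vectorised with usual recycling.  Frequencies are
#' expressed in cm^-1 of the projected pattern; the model consumes the radial
#' frequency 2 pi fx internally.
#'
#' @param mua Absorption coefficient(s), cm^-1 (> 0).
#' @param musp Reduced scattering coefficient(s), cm^-1 (> 0).
#' @param fx Spatial frequency (>= 0), cm^-1.
#' @param n Refractive index (>= 1).
#' @return Diffuse reflectance Rd, dimensionless, in [0, 1).  Strictly
#'   decreasing in \code{fx}; strictly decreasing in \code{mua} throughout
#'   the diffusion-validity regime (radial frequency 2 pi fx below roughly
#'   twice the transport coefficient — at sub-transport-length pattern
#'   periods the model's absorption sensitivity degenerates, which is also
#'   why high frequencies carry the scattering information in the inversion).
#' @examples
#' forward_reflectance(0.5, 10, fx = c(0, 0.5, 1, 2))
#' @export
forward_reflectance <- function(mua, musp, fx, n = 1.4) {
  if (any(!is.finite(mua)) || any(mua <= 0)) stop("'mua' must be positive and finite")
  if (any(!is.finite(musp)) || any(musp <= 0)) stop("'musp' must be positive and finite")
  if (any(!is.finite(fx)) || any(fx < 0)) stop("'fx' must be non-negative and finite")
  A <- (1 - effective_reflection(n)) / (2 * (1 + effective_reflection(n)))
  .rd_core(mua, musp, fx, A)
}

# unchecked core shared by the fitter (A precomputed once per map)
.rd_core <- function(mua, musp, fx, A) {
  mutr <- mua + musp
  ap <- musp / mutr
  mueffp <- sqrt(3 * mua * mutr + (2 * pi * fx)^2)
  x <- mueffp / mutr
  3 * A * ap / ((x + 1) * (x + 3 * A))
}

.boundary_A <- function(n) {
  (1 - effective_reflection(n)) / (2 * (1 + effective_reflection(n)))
}
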