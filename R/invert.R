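#' Recover absorption and reduced-scattering maps from calibrated reflectance
#'
#' Pixel-by-pixel nonlinear least squares: at every pixel and wavelength the
#' pair (mua, musp) minimises
#' \deqn{\sum_{f_x} \left[R_{d,meas}(f_x) - R_{d,model}(f_x;\ \mu_a,
#'   \mu_s')\right]^2}
#' over box bounds, using every available spatial frequency.  The low-
#' frequency end of the reflectance curve is absorption-dominated while the
#' high-frequency roll-off is scattering-dominated, which is what lets a
#' multi-frequency measurement separate the two coefficients.
#'
#' The optimiser is a damped Gauss-Newton (Levenberg-Marquardt) iteration in
#' log-parameter space, run simultaneously across all pixels with the 2 x 2
#' normal equations solved in closed form; log parameters keep the iterates
#' positive and well scaled, and steps are clamped to the declared bounds.
#' Pixels with fewer than two usable frequencies, or whose iteration fails,
#' are marked unconverged and carry NA in every output map; they propagate
#' as missing values downstream and are never in-filled.
#'
#' @param rd A \code{\link{calibrate_reflectance}} result.
#' @param n Refractive index assumed for the medium (default 1.4).
#' @param bounds List with elements \code{mua} and \code{musp}, each
#'   \code{c(lower, upper)} in cm^-1.  Defaults span tissue with margin:
#'   mua in [1e-3, 5], musp in [1, 100].
#' @param init Starting point \code{c(mua, musp)} in cm^-1.
#' @param binning Integer pixel binning factor applied to the reflectance
#'   maps before fitting (mean pooling; NA-aware).  1 = no binning.
#' @param prescan If TRUE, a coarse 20 x 20 log-spaced grid search over the
#'   bounds picks a per-pixel starting point before the refinement; guards
#'   against local minima on degenerate curves.
#' @param max_iter Maximum Levenberg-Marquardt iterations (default 200).
#' @param tol Convergence tolerance: iteration stops when the relative
#'   change in residual norm and the parameter step both fall below it.
#' @return Object of class \code{"sfdi_fit"} with per-wavelength maps
#'   \code{mua}, \code{musp} (rows, cols, wavelength; cm^-1),
#'   \code{residual_norm}, logical \code{converged}, plus the grids and
#'   settings used.  Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{fitted}, \code{predict}, \code{residuals}, \code{plot},
#'   \code{simulate}.
#' @examples
#' fx <- frequency_set(seq(0, 2.5, length.out = 5))
#' rd_curve <- forward_reflectance(0.8, 15, fx)
#' rd <- structure(list(
#'   rd = array(rep(rd_curve, each = 4), c(2, 2, 5, 1)),
#'   frequencies = fx, wavelengths = 660, n_masked = 0L),
#'   class = "calibrated_reflectance")
#' fit <- fit_optical_properties(rd)
#' coef(fit)$mua[1, 1, 1]   # ~0.8
#' @export
fit_optical_properties <- function(rd, n = 1.4,
                                   bounds = list(mua = c(1e-3, 5), musp = c(1, 100)),
                                   init = c(0.5, 15),
                                   binning = 1L, prescan = FALSE,
                                   max_iter = 200L, tol = 1e-8) {
  if (!inherits(rd, "calibrated_reflectance"))
    stop("'rd' must be a calibrated_reflectance")
  .check_bounds(bounds)
  if (length(init) != 2L || any(init <= 0)) stop("'init' must be two positive values")
  fx <- as.numeric(rd$frequencies)
  if (length(fx) < 2L) stop("at least 2 spatial frequencies are required")

  maps <- rd$rd
  if (binning > 1L) maps <- .bin_array(maps, as.integer(binning))
  dm <- dim(maps)
  nr <- dm[1]; nc <- dm[2]; nf <- dm[3]; nw <- dm[4]
  npix <- nr * nc
  A <- .boundary_A(n)

  mua <- array(NA_real_, c(nr, nc, nw))
  musp <- array(NA_real_, c(nr, nc, nw))
  resn <- array(NA_real_, c(nr, nc, nw))
  conv <- array(FALSE, c(nr, nc, nw))

  for (w in seq_len(nw)) {
    y <- matrix(maps[, , , w], npix, nf)          # measured Rd, pixels x freqs
    wt <- ifelse(is.finite(y), 1, 0)
    y[!is.finite(y)] <- 0
    usable <- rowSums(wt) >= 2
    if (!any(usable)) next
    out <- .lm_pixels(y[usable, , drop = FALSE], wt[usable, , drop = FALSE],
                      fx, A, bounds, init, prescan, max_iter, tol)
    idx <- which(usable)
    mua[, , w][idx] <- ifelse(out$conv, out$mua, NA_real_)
    musp[, , w][idx] <- ifelse(out$conv, out$musp, NA_real_)
    resn[, , w][idx] <- out$resn
    conv[, , w][idx] <- out$conv
  }

  structure(list(mua = mua, musp = musp, residual_norm = resn,
                 converged = conv, n_used = n, frequencies = frequency_set(fx),
                 wavelengths = rd$wavelengths, bounds = bounds,
                 binning = as.integer(binning), rd = maps,
                 call = match.call()),
            class = "sfdi_fit")
}

.check_bounds <- function(bounds) {
  if (!is.list(bounds) || !all(c("mua", "musp") %in% names(bounds)))
    stop("'bounds' must be a list with elements 'mua' and 'musp'")
  for (nm in c("mua", "musp")) {
    b <- bounds[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1] <= 0 || b[2] <= b[1])
      stop("bounds$", nm, " must be c(lower, upper) with 0 < lower < upper")
  }
}

# NA-aware mean pooling by factor b; trailing partial blocks are dropped
.bin_array <- function(a, b) {
  d <- dim(a)
  nr <- (d[1] %/% b) * b; nc <- (d[2] %/% b) * b
  a <- a[seq_len(nr), seq_len(nc), , , drop = FALSE]
  out <- array(NA_real_, c(nr %/% b, nc %/% b, d[3], d[4]))
  for (w in seq_len(d[4])) for (f in seq_len(d[3])) {
    m <- a[, , f, w]
    dim(m) <- c(b, nr %/% b, b, nc %/% b)
    s <- apply(m, c(2, 4), function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    out[, , f, w] <- s
  }
  out
}

# Vectorised Levenberg-Marquardt over pixels.
# y, wt: npix x nf; parameters iterated in log space, clamped to bounds.
.lm_pixels <- function(y, wt, fx, A, bounds, init, prescan, max_iter, tol) {
  npix <- nrow(y); nf <- ncol(y)
  lo <- log(c(bounds$mua[1], bounds$musp[1]))
  hi <- log(c(bounds$mua[2], bounds$musp[2]))

  cost_at <- function(u, v) {
    # u, v: npix vectors (log mua, log musp) -> residual sum of squares
    pred <- .rd_core(exp(u), exp(v), rep(fx, each = npix), A)
    dim(pred) <- c(npix, nf)
    rowSums(wt * (pred - y)^2)
  }

  if (prescan) {
    ug <- seq(lo[1], hi[1], length.out = 20)
    vg <- seq(lo[2], hi[2], length.out = 20)
    best <- rep(Inf, npix); u <- rep(ug[1], npix); v <- rep(vg[1], npix)
    for (uu in ug) for (vv in vg) {
      cc <- cost_at(rep(uu, npix), rep(vv, npix))
      take <- cc < best
      best[take] <- cc[take]; u[take] <- uu; v[take] <- vv
    }
  } else {
    u <- rep(min(max(log(init[1]), lo[1]), hi[1]), npix)
    v <- rep(min(max(log(init[2]), lo[2]), hi[2]), npix)
  }

  cost <- cost_at(u, v)
  lambda <- rep(1e-3, npix)
  active <- rep(TRUE, npix)
  h <- 1e-6
  fxr <- rep(fx, each = npix)

  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    # residuals and central-difference Jacobian in log space (all pixels at once;
    # inactive pixels ride along, cost of masking exceeds the saving at 2 params)
    pred <- .rd_core(exp(u), exp(v), fxr, A); dim(pred) <- c(npix, nf)
    r <- wt * (pred - y)
    pu1 <- .rd_core(exp(u + h), exp(v), fxr, A)
    pu2 <- .rd_core(exp(u - h), exp(v), fxr, A)
    pv1 <- .rd_core(exp(u), exp(v + h), fxr, A)
    pv2 <- .rd_core(exp(u), exp(v - h), fxr, A)
    J1 <- wt * matrix((pu1 - pu2) / (2 * h), npix, nf)
    J2 <- wt * matrix((pv1 - pv2) / (2 * h), npix, nf)
    a11 <- rowSums(J1 * J1); a12 <- rowSums(J1 * J2); a22 <- rowSums(J2 * J2)
    g1 <- rowSums(J1 * r); g2 <- rowSums(J2 * r)

    d11 <- a11 * (1 + lambda); d22 <- a22 * (1 + lambda)
    det <- d11 * d22 - a12 * a12
    det[abs(det) < 1e-300] <- NA_real_
    du <- -(d22 * g1 - a12 * g2) / det
    dv <- -(d11 * g2 - a12 * g1) / det
    bad <- !is.finite(du) | !is.finite(dv)
    du[bad] <- 0; dv[bad] <- 0

    un <- pmin(pmax(u + ifelse(active, du, 0), lo[1]), hi[1])
    vn <- pmin(pmax(v + ifelse(active, dv, 0), lo[2]), hi[2])
    costn <- cost_at(un, vn)
    improve <- active & is.finite(costn) & (costn <= cost)
    u[improve] <- un[improve]; v[improve] <- vn[improve]
    lambda[improve] <- pmax(lambda[improve] / 3, 1e-12)
    lambda[active & !improve] <- pmin(lambda[active & !improve] * 10, 1e10)

    relchange <- abs(cost - costn) / pmax(cost, 1e-300)
    stepsize <- pmax(abs(du), abs(dv))
    done <- improve & (relchange < tol) & (stepsize < sqrt(tol))
    stuck <- active & !improve & lambda >= 1e10
    cost[improve] <- costn[improve]
    active[done | stuck] <- FALSE
  }

  mua <- exp(u); musp <- exp(v)
  # fits pinned to both bounds simultaneously are degenerate, not converged
  pinned <- (u <= lo[1] & v <= lo[2]) | (u >= hi[1] & v >= hi[2])
  conv <- is.finite(cost) & !pinned
  list(mua = mua, musp = musp, resn = sqrt(cost), conv = conv)
}

#' @export
print.sfdi_fit <- function(x, ...) {
  d <- dim(x$mua)
  cat(sprintf("SFDI optical-property fit: %d x %d px, %d wavelength(s), %d frequencies, n = %g\n",
              d[1], d[2], d[3], length(x$frequencies), x$n_used))
  cat(sprintf("  converged: %.1f%% of pixels\n", 100 * mean(x$converged)))
  invisible(x)
}

#' @export
summary.sfdi_fit <- function(object, ...) {
  d <- dim(object$mua)
  per_wl <- lapply(seq_len(d[3]), function(w) {
    m <- object$mua[, , w]; s <- object$musp[, , w]; r <- object$residual_norm[, , w]
    c(wavelength_nm = object$wavelengths[w],
      n_pixels = sum(!is.na(m)),
      convergence_rate = mean(object$converged[, , w]),
      mua_median = stats::median(m, na.rm = TRUE),
      musp_median = stats::median(s, na.rm = TRUE),
      residual_q50 = stats::median(r, na.rm = TRUE),
      residual_q95 = unname(stats::quantile(r, 0.95, na.rm = TRUE)))
  })
  out <- list(table = do.call(rbind, per_wl), call = object$call)
  class(out) <- "summary.sfdi_fit"
  out
}

#' @export
print.summary.sfdi_fit <- function(x, ...) {
  cat("SFDI optical-property fit summary\n")
  print(round(x$table, 5))
  invisible(x)
}

#' @export
coef.sfdi_fit <- function(object, ...) {
  list(mua = object$mua, musp = object$musp)
}

#' Model reflectance from a fitted optical-property map
#'
#' @param object An \code{sfdi_fit}.
#' @param fx Spatial frequencies (cm^-1) at which to evaluate; defaults to
#'   the frequencies used in the fit.
#' @param ... Unused.
#' @return Array (rows, cols, length(fx), wavelength) of model Rd.
#' @export
predict.sfdi_fit <- function(object, fx = NULL, ...) {
  if (is.null(fx)) fx <- as.numeric(object$frequencies)
  d <- dim(object$mua)
  A <- .boundary_A(object$n_used)
  out <- array(NA_real_, c(d[1], d[2], length(fx), d[3]))
  for (w in seq_len(d[3])) for (f in seq_along(fx)) {
    out[, , f, w] <- .rd_core(object$mua[, , w], object$musp[, , w], fx[f], A)
  }
  out
}

#' @export
fitted.sfdi_fit <- function(object, ...) predict(object)

#' @export
residuals.sfdi_fit <- function(object, ...) {
  object$rd - fitted(object)
}

#' @export
plot.sfdi_fit <- function(x, wavelength_index = 1L,
                          which = c("mua", "musp"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(which)), mar = c(2, 2, 3, 1))
  on.exit(graphics::par(op))
  for (nm in which) {
    m <- x[[nm]][, , wavelength_index]
    graphics::image(t(m[nrow(m):1, ]), axes = FALSE, useRaster = TRUE,
                    col = grDevices::hcl.colors(64, "viridis"),
                    main = sprintf("%s (cm^-1), %g nm", nm,
                                   x$wavelengths[wavelength_index]), ...)
  }
  invisible(x)
}

#' Simulate noisy reflectance curves from a fitted map
#'
#' Draws multiplicative Gaussian noise around the model reflectance implied
#' by the fitted per-pixel properties — useful for parametric-bootstrap style
#' checks of the inversion.
#'
#' @param object An \code{sfdi_fit}.
#' @param nsim Number of replicate arrays.
#' @param seed Optional integer seed.
#' @param sigma Relative noise standard deviation (default 0.01).
#' @param ... Unused.
#' @return List of \code{nsim} arrays shaped like \code{fitted(object)}.
#' @export
simulate.sfdi_fit <- function(object, nsim = 1, seed = NULL, sigma = 0.01, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  lapply(seq_len(nsim), function(i) {
    mu * (1 + stats::rnorm(length(mu), 0, sigma))
  })
}
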