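# Independent oracles used to verify the implementation by a different
# computational route.  Nothing here calls the package's model internals
# beyond the public surface under test.

# Numerical solve of the 1D modulated diffusion boundary-value problem:
#   -phi'' + mueffp^2 phi = 3 musp mutr exp(-mutr z)  on [0, zmax]
#   Robin (partial-current) BC at the surface: -D phi'(0) = A phi(0)
#   phi(zmax) = 0;  reflectance Rd = A phi(0)
# Second-order finite differences with a ghost point for the Robin BC,
# plus Richardson extrapolation over two grids.
bvp_reflectance_oracle <- function(mua, musp, fx, n = 1.4, N = 15000) {
  mutr <- mua + musp
  D <- 1 / (3 * mutr)
  Reff <- 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
  A <- (1 - Reff) / (2 * (1 + Reff))
  mueffp2 <- 3 * mua * mutr + (2 * pi * fx)^2
  zmax <- 20 / min(sqrt(mueffp2), mutr)
  solve_grid <- function(N) {
    h <- zmax / N
    z <- (0:(N - 1)) * h
    q <- 3 * musp * mutr * exp(-mutr * z)
    main <- rep(2 / h^2, N) + mueffp2
    main[1] <- main[1] + (2 * A / D) / h
    lower <- rep(-1 / h^2, N - 1)
    upper <- c(-2 / h^2, rep(-1 / h^2, N - 2))
    M <- Matrix::bandSparse(N, N, k = c(-1, 0, 1),
                            diagonals = list(lower, main, upper))
    phi <- Matrix::solve(M, q)
    A * phi[1]
  }
  r1 <- solve_grid(N)
  r2 <- solve_grid(2 * N)
  as.numeric((4 * r2 - r1) / 3)
}

# Per-pixel least-squares sinusoid amplitude: fit I_k = a + b cos(ph_k) +
# c sin(ph_k) by lm() and return sqrt(b^2 + c^2).
lsq_sinusoid_amplitude <- function(i1, i2, i3) {
  ph <- c(0, 2 * pi / 3, 4 * pi / 3)
  X <- cbind(1, cos(ph), sin(ph))
  vapply(seq_along(i1), function(k) {
    b <- stats::lm.fit(X, c(i1[k], i2[k], i3[k]))$coefficients
    unname(sqrt(b[2]^2 + b[3]^2))
  }, numeric(1))
}

# Dense grid search over the fit bounds; a second pass refines around the
# coarse argmin (the residual valley is long and shallow, so the coarse
# argmin alone can sit a cell or two along it).  Brute-force reference for
# the per-pixel optimiser; returns the coarse cell size as the comparison
# scale.
grid_search_op <- function(rd_meas, fx, n = 1.4,
                           mua_range = c(1e-3, 5), musp_range = c(1, 100),
                           ngrid = 400) {
  scan <- function(mua_lim, musp_lim) {
    mua_g <- seq(mua_lim[1], mua_lim[2], length.out = ngrid)
    musp_g <- seq(musp_lim[1], musp_lim[2], length.out = ngrid)
    best <- Inf
    bi <- bj <- 1L
    for (j in seq_along(musp_g)) {
      cost <- rowSums((vapply(seq_along(fx), function(fi)
        forward_reflectance(mua_g, musp_g[j], fx[fi], n), numeric(ngrid)) -
          matrix(rd_meas, ngrid, length(fx), byrow = TRUE))^2)
      jmin <- which.min(cost)
      if (cost[jmin] < best) {
        best <- cost[jmin]; bi <- jmin; bj <- j
      }
    }
    list(mua = mua_g[bi], musp = musp_g[bj],
         cell = c(diff(mua_g[1:2]), diff(musp_g[1:2])))
  }
  coarse <- scan(mua_range, musp_range)
  fine <- scan(pmax(mua_range[1],
                    c(coarse$mua - 3 * coarse$cell[1],
                      coarse$mua + 3 * coarse$cell[1])),
               pmax(musp_range[1],
                    c(coarse$musp - 3 * coarse$cell[2],
                      coarse$musp + 3 * coarse$cell[2])))
  list(mua = fine$mua, musp = fine$musp, cell = coarse$cell)
}

# Explicit pixel-enumeration ROI statistics (loop, no vectorisation).
roi_enum_oracle <- function(map, mask) {
  vals <- c()
  for (r in seq_len(nrow(map))) for (cc in seq_len(ncol(map))) {
    if (mask[r, cc] && !is.na(map[r, cc])) vals <- c(vals, map[r, cc])
  }
  m <- sum(vals) / length(vals)
  list(mean = m, std = sqrt(sum((vals - m)^2) / length(vals)),
       n_pixels = length(vals))
}

# Build a calibrated_reflectance object directly from per-pixel truth maps
# (bypasses rendering; used to test the inverter in isolation).
make_rd_object <- function(mua, musp, fx, n = 1.4, noise_sigma = 0) {
  nr <- nrow(mua); nc <- ncol(mua)
  rd <- array(NA_real_, c(nr, nc, length(fx), 1))
  for (f in seq_along(fx))
    rd[, , f, 1] <- forward_reflectance(mua, musp, fx[f], n)
  if (noise_sigma > 0)
    rd <- rd * (1 + stats::rnorm(length(rd), 0, noise_sigma))
  structure(list(rd = rd, frequencies = frequency_set(fx),
                 wavelengths = 660, n_masked = 0L),
            class = "calibrated_reflectance")
}
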