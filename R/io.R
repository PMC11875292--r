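# File formats: multi-page 32-bit TIFF for image data, with a JSON sidecar
# (same basename, .json) as the single source of truth for page ordering,
# physical units and the scale factor.  TIFF stores [0,1]; every writer
# divides by a recorded `scale` and NA pixels are encoded as 0 in the data
# pages plus companion validity-mask pages appended after the data pages.

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a numeric map (matrix or array) as scaled multi-page TIFF + sidecar
#'
#' @param x Matrix or 3-D array; NA allowed.
#' @param path Output .tif path; the sidecar is written next to it.
#' @param scale Scale factor; defaults to the finite maximum (or 1).
#' @param units Unit string recorded in the sidecar.
#' @return Invisibly, the sidecar list.
#' @export
write_sfdi_tiff <- function(x, path, scale = NULL, units = "arbitrary") {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("'x' must be a matrix or 3-D array")
  if (is.null(scale)) {
    mx <- suppressWarnings(max(x, na.rm = TRUE))
    scale <- if (is.finite(mx) && mx > 0) mx else 1
  }
  np <- dim(x)[3]
  pages <- vector("list", 2L * np)
  for (i in seq_len(np)) {
    m <- x[, , i] / scale
    mask <- is.finite(m)
    m[!mask] <- 0
    pages[[i]] <- pmin(pmax(m, 0), 1)
    pages[[np + i]] <- mask * 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(format = "sfdiq-map", n_pages = np, dim = dim(x)[1:2],
               scale = scale, units = units, masked = TRUE)
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a map written by \code{\link{write_sfdi_tiff}}
#'
#' @param path .tif path with its JSON sidecar alongside.
#' @return 3-D array (rows, cols, pages) with NA restored and the sidecar
#'   attached as attribute \code{"sidecar"}.
#' @export
read_sfdi_tiff <- function(path) {
  side <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  np <- side$n_pages
  if (length(pages) != 2L * np) stop("page count does not match sidecar")
  out <- array(NA_real_, c(dim(pages[[1L]]), np))
  for (i in seq_len(np)) {
    m <- pages[[i]] * side$scale
    m[pages[[np + i]] < 0.5] <- NA_real_
    out[, , i] <- m
  }
  attr(out, "sidecar") <- side
  out
}

#' Write an acquisition stack as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered phase-fastest, then frequency, then wavelength; the
#' sidecar declares the ordering, the frequency list (cm^-1), wavelength
#' centers (nm), the intensity scale and the acquisition metadata.  A dark
#' frame, when present, goes to \code{<name>_dark.tif}.
#'
#' @param stack An \code{\link{acquisition_stack}}.
#' @param dir Output directory (created if needed).
#' @param name Basename (default "stack").
#' @return Invisibly, the main TIFF path.
#' @export
write_acquisition <- function(stack, dir, name = "stack") {
  if (!inherits(stack, "acquisition_stack")) stop("'stack' must be an acquisition_stack")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$images)
  scale <- if (!is.null(stack$meta$full_scale)) stack$meta$full_scale else
    max(stack$images, 1)
  pages <- vector("list", d[3] * d[4] * d[5])
  i <- 0L
  for (w in seq_len(d[5])) for (f in seq_len(d[4])) for (p in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- pmin(pmax(stack$images[, , p, f, w] / scale, 0), 1)
  }
  path <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  if (!is.null(stack$dark))
    tiff::writeTIFF(pmin(pmax(stack$dark / scale, 0), 1),
                    file.path(dir, paste0(name, "_dark.tif")),
                    bits.per.sample = 32L)
  side <- list(format = "sfdiq-stack",
               page_order = "phase-fastest, then frequency, then wavelength",
               n_phases = 3, phases_rad = c(0, 2 * pi / 3, 4 * pi / 3),
               frequencies_cm1 = as.numeric(stack$frequencies),
               wavelengths_nm = stack$wavelengths,
               dim = d[1:2], scale = scale,
               units = list(length = "cm", frequency = "cm^-1",
                            wavelength = "nm", intensity = "camera"),
               dark = !is.null(stack$dark),
               meta = stack$meta)
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an acquisition stack written by \code{\link{write_acquisition}}
#'
#' @param dir Directory containing \code{<name>.tif} and sidecar.
#' @param name Basename (default "stack").
#' @return An \code{\link{acquisition_stack}}.
#' @export
read_acquisition <- function(dir, name = "stack") {
  path <- file.path(dir, paste0(name, ".tif"))
  side <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nf <- length(side$frequencies_cm1); nw <- length(side$wavelengths_nm)
  if (length(pages) != 3L * nf * nw) stop("page count does not match sidecar")
  d1 <- dim(pages[[1L]])
  img <- array(0, c(d1[1], d1[2], 3, nf, nw))
  i <- 0L
  for (w in seq_len(nw)) for (f in seq_len(nf)) for (p in 1:3) {
    i <- i + 1L
    img[, , p, f, w] <- pages[[i]] * side$scale
  }
  dark_path <- file.path(dir, paste0(name, "_dark.tif"))
  dark <- if (isTRUE(side$dark) && file.exists(dark_path))
    tiff::readTIFF(dark_path) * side$scale else NULL
  meta <- as.list(side$meta)
  acquisition_stack(img, frequency_set(side$frequencies_cm1),
                    side$wavelengths_nm, dark = dark, meta = meta)
}

#' Write a demodulated set (AC maps, DC maps, saturation mask)
#'
#' @param demod A \code{\link{demodulate}} result.
#' @param dir Output directory.
#' @param name Basename prefix.
#' @return Invisibly, \code{dir}.
#' @export
write_demodulated <- function(demod, dir, name = "demod") {
  if (!inherits(demod, "demodulated_set")) stop("'demod' must be a demodulated_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(demod$mac)
  mac <- array(demod$mac, c(d[1], d[2], d[3] * d[4]))
  sc <- max(mac, 1)
  write_sfdi_tiff(mac, file.path(dir, paste0(name, "_mac.tif")), scale = sc)
  write_sfdi_tiff(array(demod$mdc, c(d[1], d[2], d[4])),
                  file.path(dir, paste0(name, "_mdc.tif")), scale = sc)
  write_sfdi_tiff(demod$saturation_mask * 1,
                  file.path(dir, paste0(name, "_sat.tif")), scale = 1)
  side <- list(format = "sfdiq-demod",
               frequencies_cm1 = as.numeric(demod$frequencies),
               wavelengths_nm = demod$wavelengths, meta = demod$meta)
  jsonlite::write_json(side, file.path(dir, paste0(name, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a demodulated set written by \code{\link{write_demodulated}}
#'
#' @param dir Directory.
#' @param name Basename prefix.
#' @return A \code{demodulated_set}.
#' @export
read_demodulated <- function(dir, name = "demod") {
  side <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
                              simplifyVector = TRUE)
  nf <- length(side$frequencies_cm1); nw <- length(side$wavelengths_nm)
  mac <- read_sfdi_tiff(file.path(dir, paste0(name, "_mac.tif")))
  mdc <- read_sfdi_tiff(file.path(dir, paste0(name, "_mdc.tif")))
  sat <- read_sfdi_tiff(file.path(dir, paste0(name, "_sat.tif")))
  d1 <- dim(mac)[1:2]
  structure(list(mac = array(mac, c(d1, nf, nw)),
                 mdc = array(mdc, c(d1, nw)),
                 saturation_mask = matrix(sat[, , 1] > 0.5, d1[1], d1[2]),
                 frequencies = frequency_set(side$frequencies_cm1),
                 wavelengths = side$wavelengths_nm,
                 meta = as.list(side$meta)),
            class = "demodulated_set")
}

#' Write fitted optical-property maps (TIFF) and a fit summary (CSV)
#'
#' @param fit An \code{\link{fit_optical_properties}} result.
#' @param dir Output directory.
#' @return Invisibly, \code{dir}.
#' @export
write_op_fit <- function(fit, dir) {
  if (!inherits(fit, "sfdi_fit")) stop("'fit' must be an sfdi_fit")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sfdi_tiff(fit$mua, file.path(dir, "mua.tif"), units = "cm^-1")
  write_sfdi_tiff(fit$musp, file.path(dir, "musp.tif"), units = "cm^-1")
  write_sfdi_tiff(fit$residual_norm, file.path(dir, "residual.tif"))
  write_sfdi_tiff(fit$converged * 1, file.path(dir, "converged.tif"), scale = 1)
  utils::write.csv(as.data.frame(summary(fit)$table),
                   file.path(dir, "fit_summary.csv"), row.names = FALSE)
  side <- list(format = "sfdiq-opmap", wavelengths_nm = fit$wavelengths,
               frequencies_cm1 = as.numeric(fit$frequencies),
               n = fit$n_used, binning = fit$binning,
               bounds = fit$bounds)
  jsonlite::write_json(side, file.path(dir, "opmap_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read reference-phantom optical properties from YAML
#'
#' The YAML maps wavelength (nm) to \code{mua_cm1}, \code{musp_cm1} and
#' optionally \code{n}:
#' \preformatted{
#' "490": {mua_cm1: 0.5, musp_cm1: 10, n: 1.4}
#' "590": {mua_cm1: 0.4, musp_cm1: 9}
#' }
#'
#' @param path YAML file path.
#' @param default_n Refractive index used when an entry omits \code{n}.
#' @return Named list (wavelength as name) of
#'   \code{\link{optical_properties}}.
#' @export
read_reference_properties <- function(path, default_n = 1.4) {
  y <- yaml::read_yaml(path)
  if (length(y) == 0L) stop("empty reference-properties file")
  out <- lapply(y, function(e) {
    # YAML 1.1 reads a bare key `n` as boolean FALSE; restore it
    names(e)[names(e) %in% c("FALSE", "false")] <- "n"
    if (is.null(e$mua_cm1) || is.null(e$musp_cm1))
      stop("each wavelength entry needs mua_cm1 and musp_cm1")
    optical_properties(e$mua_cm1, e$musp_cm1,
                       if (is.null(e$n)) default_n else e$n)
  })
  names(out) <- names(y)
  out
}

#' Read an ROI from JSON
#'
#' Accepts \code{\{name, vertices: [[row, col], ...]\}} or
#' \code{\{name, mask_tiff: path\}} (path relative to the JSON file).
#'
#' @param path JSON file path.
#' @return An \code{\link{roi_polygon}}.
#' @export
read_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$name)) stop("ROI JSON must have a 'name'")
  if (!is.null(j$vertices)) {
    v <- matrix(as.numeric(as.matrix(j$vertices)), ncol = 2)
    return(roi_polygon(j$name, vertices = v))
  }
  if (!is.null(j$mask_tiff)) {
    mp <- if (file.exists(j$mask_tiff)) j$mask_tiff else
      file.path(dirname(path), j$mask_tiff)
    m <- tiff::readTIFF(mp)
    return(roi_polygon(j$name, mask = m > 0.5))
  }
  stop("ROI JSON must contain 'vertices' or 'mask_tiff'")
}

#' Write an ROI polygon to JSON
#'
#' @param roi An \code{\link{roi_polygon}} with vertices.
#' @param path Output path.
#' @export
write_roi <- function(roi, path) {
  if (!inherits(roi, "roi_polygon") || is.null(roi$vertices))
    stop("'roi' must be a polygon roi_polygon")
  jsonlite::write_json(list(name = roi$name,
                            vertices = unname(apply(roi$vertices, 1, as.list))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a fluorescence calibration curve to JSON
#'
#' @param cal A \code{\link{fit_fluor_calibration}} object.
#' @param path Output path.
#' @param ex_nm,em_nm Excitation/emission wavelengths, nm.
#' @param ref_props Optional list with the calibration phantom's optical
#'   properties at both wavelengths, e.g.
#'   \code{list(ex = optical_properties(...), em = ...)}.
#' @export
write_fluor_calibration <- function(cal, path, ex_nm = NA, em_nm = NA,
                                    ref_props = NULL) {
  if (!inherits(cal, "fluor_calibration")) stop("'cal' must be a fluor_calibration")
  rp <- if (!is.null(ref_props))
    lapply(ref_props, function(p) list(mua_cm1 = p$mua, musp_cm1 = p$musp, n = p$n))
  jsonlite::write_json(list(concentrations_ug_ml = cal$concentrations,
                            fcorr_values = cal$fcorr,
                            slope = cal$slope, intercept = cal$intercept,
                            r2 = cal$r_squared, ex_nm = ex_nm, em_nm = em_nm,
                            ref_props = rp),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fluorescence calibration curve from JSON
#'
#' @param path JSON path written by \code{\link{write_fluor_calibration}}.
#' @return A \code{fluor_calibration} (refit from the stored points when
#'   present, otherwise reconstructed from slope/intercept), with
#'   \code{ex_nm}, \code{em_nm} and \code{ref_props} attached as attributes.
#' @export
read_fluor_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cal <- if (!is.null(j$concentrations_ug_ml) && length(j$concentrations_ug_ml) >= 2) {
    fit_fluor_calibration(j$concentrations_ug_ml, j$fcorr_values)
  } else {
    structure(list(slope = j$slope, intercept = j$intercept,
                   r_squared = j$r2, concentrations = NULL, fcorr = NULL,
                   lm = NULL), class = "fluor_calibration")
  }
  attr(cal, "ex_nm") <- j$ex_nm
  attr(cal, "em_nm") <- j$em_nm
  attr(cal, "ref_props") <- j$ref_props
  cal
}
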