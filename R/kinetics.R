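#' Region of interest as a polygon or explicit mask
#'
#' ROIs delineate tumor, periphery or injection-site regions on a map.  A
#' polygon ROI is rasterized with the even-odd rule applied to pixel centers
#' (pixel (r, c) has center (r, c) in 1-based row/col coordinates), which
#' makes ROI statistics deterministic and portable.
#'
#' @param name Label, e.g. "tumor".
#' @param vertices Two-column matrix of polygon vertices as (row, col) pixel
#'   coordinates, or NULL when a mask is given.
#' @param mask Optional logical matrix used directly instead of a polygon.
#' @return Object of class \code{"roi_polygon"}.
#' @export
roi_polygon <- function(name, vertices = NULL, mask = NULL) {
  if (is.null(vertices) && is.null(mask))
    stop("supply polygon 'vertices' or a logical 'mask'")
  if (!is.null(vertices)) {
    vertices <- as.matrix(vertices)
    if (ncol(vertices) != 2L || nrow(vertices) < 3L)
      stop("'vertices' must be an n x 2 matrix with n >= 3")
    if (anyNA(vertices)) stop("'vertices' must be finite")
  }
  if (!is.null(mask) && !is.logical(mask)) stop("'mask' must be logical")
  structure(list(name = name, vertices = vertices, mask = mask),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  if (is.null(x$mask))
    cat(sprintf("ROI '%s': polygon with %d vertices\n", x$name, nrow(x$vertices)))
  else
    cat(sprintf("ROI '%s': explicit mask, %d pixel(s)\n", x$name, sum(x$mask)))
  invisible(x)
}

#' Rasterize an ROI to a logical mask
#'
#' @param roi An \code{\link{roi_polygon}} or a logical matrix.
#' @param dim Image dimensions \code{c(rows, cols)}.
#' @return Logical matrix; errors if the rasterization is empty.
#' @export
as_roi_mask <- function(roi, dim) {
  if (is.logical(roi) && is.matrix(roi)) {
    if (!all(base::dim(roi) == dim)) stop("mask shape does not match image")
    return(roi)
  }
  if (!inherits(roi, "roi_polygon")) stop("'roi' must be an roi_polygon or logical matrix")
  if (!is.null(roi$mask)) {
    if (!all(base::dim(roi$mask) == dim)) stop("ROI mask shape does not match image")
    m <- roi$mask
  } else {
    m <- .rasterize_polygon(roi$vertices, dim[1], dim[2])
  }
  if (!any(m)) stop("ROI '", roi$name, "' rasterizes to an empty mask")
  m
}

# even-odd (crossing number) point-in-polygon test at pixel centers,
# vectorised over all pixels
.rasterize_polygon <- function(v, nr, nc) {
  py <- rep(seq_len(nr), times = nc)   # row coordinate of each pixel center
  px <- rep(seq_len(nc), each = nr)    # col coordinate
  nvert <- nrow(v)
  inside <- logical(nr * nc)
  j <- nvert
  for (i in seq_len(nvert)) {
    yi <- v[i, 1]; xi <- v[i, 2]
    yj <- v[j, 1]; xj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nr, nc)
}

#' ROI summary statistics
#'
#' Mean and population standard deviation (divide by n, not n - 1) of the
#' unmasked (non-NA) pixels inside the ROI.
#'
#' @param map Numeric matrix (concentration or optical-property map); NA
#'   pixels are excluded.
#' @param roi \code{\link{roi_polygon}} or logical mask.
#' @return List with \code{mean}, \code{std}, \code{n_pixels}.
#' @examples
#' m <- matrix(7, 10, 10)
#' roi_stats(m, roi_polygon("all", rbind(c(1, 1), c(1, 10), c(10, 10), c(10, 1))))
#' @export
roi_stats <- function(map, roi) {
  sel <- as_roi_mask(roi, dim(map))
  vals <- map[sel & !is.na(map)]
  if (length(vals) == 0L) stop("ROI contains no unmasked pixels")
  m <- mean(vals)
  list(mean = m, std = sqrt(mean((vals - m)^2)), n_pixels = length(vals))
}

#' Percent change between two ROI means
#'
#' \code{100 * (pre - post) / pre}; positive values are decreases (e.g.
#' photobleaching), negative values increases (e.g. drug release).
#'
#' @param pre_mean Pre-treatment mean (> 0).
#' @param post_mean Post-treatment mean.
#' @return Percent change.
#' @examples
#' percent_change(1.57, 0.73)   # ~53.5% photobleaching decrease
#' @export
percent_change <- function(pre_mean, post_mean) {
  if (any(!is.finite(pre_mean)) || any(pre_mean <= 0))
    stop("'pre_mean' must be positive")
  100 * (pre_mean - post_mean) / pre_mean
}

#' Contrast ratio between two ROI means
#'
#' @param roi_a_mean Numerator mean (e.g. tumor).
#' @param roi_b_mean Denominator mean (> 0; e.g. normal tissue).
#' @return \code{roi_a_mean / roi_b_mean}.
#' @examples
#' contrast_ratio(0.24, 0.183)   # ~1.31 tumor-to-periphery uptake ratio
#' @export
contrast_ratio <- function(roi_a_mean, roi_b_mean) {
  if (any(!is.finite(roi_b_mean)) || any(roi_b_mean <= 0))
    stop("denominator mean must be positive")
  roi_a_mean / roi_b_mean
}

#' Time-resolved ROI release curve with plateau detection
#'
#' Computes the ROI mean and standard deviation of a time-ordered sequence
#' of concentration maps, then finds the plateau: the earliest time point
#' after which every consecutive relative increase stays below
#' \code{plateau_threshold}.  A constant series plateaus at the first time
#' point; a strictly growing series (all increments above threshold) never
#' plateaus and \code{plateau_time} is NA.
#'
#' @param maps List of concentration maps (matrices, common shape).
#' @param times Numeric vector of acquisition times in minutes, strictly
#'   increasing, same length as \code{maps}.
#' @param roi \code{\link{roi_polygon}} or logical mask.
#' @param plateau_threshold Relative-increment threshold (default 0.02).
#' @return Object of class \code{"kinetics_series"}: list with \code{times},
#'   \code{means}, \code{stds}, \code{n_pixels}, \code{plateau_time},
#'   \code{roi_name}.
#' @export
release_curve <- function(maps, times, roi, plateau_threshold = 0.02) {
  if (length(maps) < 2L) stop("at least 2 time points are required")
  if (length(times) != length(maps)) stop("'times' and 'maps' lengths differ")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  d <- dim(maps[[1L]])
  if (!all(vapply(maps, function(m) all(dim(m) == d), logical(1))))
    stop("all maps must share one shape")
  st <- lapply(maps, roi_stats, roi = roi)
  means <- vapply(st, `[[`, numeric(1), "mean")
  stds <- vapply(st, `[[`, numeric(1), "std")
  npix <- vapply(st, `[[`, numeric(1), "n_pixels")

  rel_inc <- diff(means) / ifelse(abs(means[-length(means)]) > 0,
                                  abs(means[-length(means)]), Inf)
  below <- rel_inc < plateau_threshold
  # earliest time point from which every remaining increment stays below the
  # threshold; the final point alone is vacuous, so it never counts as a
  # plateau on its own
  plateau_time <- NA_real_
  for (i in seq_along(below)) {
    if (all(below[i:length(below)])) {
      plateau_time <- times[i]
      break
    }
  }
  structure(list(times = times, means = means, stds = stds, n_pixels = npix,
                 plateau_time = plateau_time,
                 plateau_threshold = plateau_threshold,
                 roi_name = if (inherits(roi, "roi_polygon")) roi$name else "mask"),
            class = "kinetics_series")
}

#' @export
print.kinetics_series <- function(x, ...) {
  cat(sprintf("release kinetics over ROI '%s': %d time points, %g-%g min\n",
              x$roi_name, length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  plateau: %s\n",
              if (is.na(x$plateau_time)) "not reached"
              else sprintf("reached at %g min", x$plateau_time)))
  invisible(x)
}

#' @export
plot.kinetics_series <- function(x, ...) {
  graphics::plot(x$times, x$means, type = "b", pch = 16,
                 xlab = "time (min)", ylab = "ROI mean concentration (ug/mL)",
                 main = sprintf("release kinetics: %s", x$roi_name), ...)
  graphics::arrows(x$times, x$means - x$stds, x$times, x$means + x$stds,
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  if (!is.na(x$plateau_time))
    graphics::abline(v = x$plateau_time, lty = 2, col = "red")
  invisible(x)
}

#' @export
as.data.frame.kinetics_series <- function(x, ...) {
  data.frame(time_min = x$times, mean_ug_ml = x$means, std_ug_ml = x$stds,
             n_pixels = x$n_pixels)
}
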