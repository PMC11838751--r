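#' Hemisphere electrode subset of a 16-electrode layout
#'
#' The upper-view subset comprises the eight equatorial electrodes plus
#' the four upper-ring electrodes; the lower view mirrors it.
#'
#' @param layout an \code{\link{shell_layout}}.
#' @param view \code{"upper"} or \code{"lower"}.
#' @return logical vector marking the 12-electrode subset.
#' @export
hemisphere_subset <- function(layout, view = c("upper", "lower")) {
  view <- match.arg(view)
  if (view == "upper") layout$lat >= 0 else layout$lat <= 0
}

#' Project a hemisphere of the interpolated LAT field to a 2D image
#'
#' Re-interpolates the LATs using only the 12 electrodes of the chosen
#' hemisphere (eight equatorial plus the four polar-ring electrodes),
#' then orthographically projects the visible hemisphere along the polar
#' axis onto a pixel grid. The projection is analytic (each pixel centre
#' is mapped to its point on the sphere and the interpolant evaluated
#' there), so it is deterministic and free of any rendering round trip.
#'
#' @param layout an \code{\link{shell_layout}} (16 electrodes).
#' @param node_lats per-electrode LATs, s, aligned with \code{layout}.
#' @param view \code{"upper"} or \code{"lower"}.
#' @param n_px image side length, pixels.
#' @param pixel_size_um microns per pixel; default scales the projected
#'   disk to fill ~90\% of the image.
#' @param epsilon RBF shape parameter; default from the 12-electrode
#'   subset.
#' @return object of class \code{projection_map}: list with \code{lat}
#'   (n_px x n_px matrix, s, NA outside the disk), \code{valid},
#'   \code{pixel_size_um}, \code{view}.
#' @export
project_hemisphere <- function(layout, node_lats, view = c("upper", "lower"),
                               n_px = 64, pixel_size_um = NULL,
                               epsilon = NULL) {
  view <- match.arg(view)
  stopifnot(inherits(layout, "electrode_layout"),
            length(node_lats) == nrow(layout))
  sel <- hemisphere_subset(layout, view)
  if (sum(sel) < 12)
    stop("project_hemisphere: fewer than 12 electrodes in the ", view,
         " hemisphere subset")
  if (any(!is.finite(node_lats[sel])))
    stop("project_hemisphere: non-finite LAT among the subset electrodes")
  r <- attr(layout, "radius_cm")
  if (is.null(pixel_size_um)) pixel_size_um <- 2 * r * 1e4 / (0.9 * n_px)
  sub <- layout[sel, , drop = FALSE]
  attr(sub, "radius_cm") <- r
  class(sub) <- c("electrode_layout", "data.frame")
  if (is.null(epsilon)) epsilon <- default_epsilon(sub)
  pc <- orthographic_pixel_coords(n_px, pixel_size_um, r, view)
  img <- matrix(NA_real_, n_px, n_px)
  ok <- pc$inside
  img[ok] <- interpolate_lat(pc$lat[ok], pc$lon[ok], sub, node_lats[sel],
                             epsilon)
  structure(list(lat = img, valid = ok, pixel_size_um = pixel_size_um,
                 view = view, epsilon = epsilon),
            class = "projection_map")
}

#' @export
print.projection_map <- function(x, ...) {
  cat(sprintf("%s-view projection: %d x %d px (%.3g um/px), LAT %.2f-%.2f ms\n",
              x$view, nrow(x$lat), ncol(x$lat), x$pixel_size_um,
              1e3 * min(x$lat, na.rm = TRUE), 1e3 * max(x$lat, na.rm = TRUE)))
  invisible(x)
}

#' Compare two 2D LAT maps: Pearson correlation and MAE
#'
#' Computed over pixels valid in both maps. The mean absolute error is
#' expressed as a percentage of the reference map's LAT range, so
#' \code{compare_maps(a, b)} and \code{compare_maps(b, a)} share the same
#' correlation but normalise MAE differently (the reference is always the
#' second argument).
#'
#' @param a,b matrices of LATs (s), NA = invalid, identical dimensions
#'   (rescale first with \code{\link{rescale_map}} if needed). Accepts
#'   \code{pixel_lat_map}/\code{projection_map} objects.
#' @param min_pixels minimum number of co-valid pixels (default 10).
#' @return list with \code{pearson_r}, \code{mae_percent}, \code{mae_s},
#'   \code{n_pixels}.
#' @export
compare_maps <- function(a, b, min_pixels = 10) {
  if (is.list(a)) a <- a$lat
  if (is.list(b)) b <- b$lat
  if (!all(dim(a) == dim(b)))
    stop("compare_maps: maps must share pixel dimensions")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < min_pixels)
    stop("compare_maps: fewer than ", min_pixels, " co-valid pixels")
  av <- a[ok]; bv <- b[ok]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("compare_maps: zero variance in one map; correlation undefined")
  mae <- mean(abs(av - bv))
  list(pearson_r = stats::cor(av, bv),
       mae_percent = 100 * mae / diff(range(bv)),
       mae_s = mae, n_pixels = sum(ok))
}

#' Rescale a 2D LAT map to new pixel dimensions
#'
#' Nearest-neighbour resampling (sufficient for matching map dimensions
#' before \code{\link{compare_maps}}; no inter-modality warping is done).
#'
#' @param m matrix (NA = invalid) or an object with a \code{lat} element.
#' @param dim_out target \code{c(rows, cols)}.
#' @return resampled matrix.
#' @export
rescale_map <- function(m, dim_out) {
  if (is.list(m)) m <- m$lat
  ri <- pmin(nrow(m), pmax(1, round(seq(1, nrow(m), length.out = dim_out[1]))))
  ci <- pmin(ncol(m), pmax(1, round(seq(1, ncol(m), length.out = dim_out[2]))))
  m[ri, ci, drop = FALSE]
}

#' Compare conduction-velocity distributions across fields
#'
#' @param ... named \code{cv_field} / \code{cv_field2d} objects.
#' @param breaks histogram breaks passed to \code{\link[graphics]{hist}}
#'   (computed, not plotted).
#' @return data frame with one row per field: n_valid, mean, median, sd
#'   of the valid speeds (cm/s); histograms as an attribute.
#' @export
compare_cv <- function(..., breaks = 30) {
  fields <- list(...)
  if (is.null(names(fields)) || any(names(fields) == ""))
    names(fields) <- paste0("field", seq_along(fields))
  rows <- lapply(names(fields), function(nm) {
    f <- fields[[nm]]
    sp <- f$speed[f$valid]
    if (length(sp) == 0) stop("compare_cv: field '", nm, "' has no valid nodes")
    data.frame(field = nm, n_valid = length(sp), mean = mean(sp),
               median = stats::median(sp), sd = stats::sd(sp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- lapply(fields, function(f)
    graphics::hist(f$speed[f$valid], breaks = breaks, plot = FALSE))
  out
}
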