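#' Great-circle (haversine) distance on a sphere
#'
#' Distance between points given as (latitude, longitude) pairs in radians
#' on a sphere of radius \code{r}:
#' \deqn{d = 2 r \arcsin\sqrt{\sin^2(\Delta\phi/2) +
#'   \cos\phi_1\cos\phi_2\sin^2(\Delta\lambda/2)}}
#' The argument of \code{asin} is clipped to [0, 1] to guard against
#' floating-point rounding for near-antipodal points.
#'
#' @param lat1,lon1 latitude/longitude of the first point(s), radians.
#' @param lat2,lon2 latitude/longitude of the second point(s), radians.
#' @param r sphere radius (any length unit; the distance inherits it).
#' @return great-circle distance(s), same unit as \code{r}. Vectorised with
#'   the usual recycling rules.
#' @examples
#' haversine(0, 0, 0, pi / 2, r = 0.025)  # quarter great circle
#' @export
haversine <- function(lat1, lon1, lat2, lon2, r) {
  if (any(!is.finite(c(lat1, lon1, lat2, lon2))))
    stop("haversine: coordinates must be finite")
  if (!is.numeric(r) || any(r <= 0)) stop("haversine: r must be > 0")
  a <- sin((lat2 - lat1) / 2)^2 +
    cos(lat1) * cos(lat2) * sin((lon2 - lon1) / 2)^2
  2 * r * asin(sqrt(pmin(pmax(a, 0), 1)))
}

#' Standard 16-electrode shell MEA layout
#'
#' The folded shell MEA contacts the organoid on three rings: four
#' equidistant electrodes near the bottom, eight at the equator and four
#' near the top. The polar rings sit at latitude +/- 45 degrees by default
#' (the ring latitudes are a device property and can be overridden).
#'
#' @param radius_cm sphere (organoid) radius in cm; default 0.025 cm
#'   (250 um, a 500 um-diameter organoid).
#' @param ring_lat_deg latitude of the upper polar ring in degrees; the
#'   lower ring mirrors it.
#' @return object of class \code{electrode_layout}: data frame with columns
#'   \code{channel_id}, \code{lat}, \code{lon} (radians) plus attribute
#'   \code{radius_cm}.
#' @export
shell_layout <- function(radius_cm = 0.025, ring_lat_deg = 45) {
  deg <- pi / 180
  lower <- data.frame(lat = -ring_lat_deg * deg,
                      lon = c(0, 90, 180, 270) * deg)
  equator <- data.frame(lat = 0, lon = seq(0, 315, by = 45) * deg)
  upper <- data.frame(lat = ring_lat_deg * deg,
                      lon = c(0, 90, 180, 270) * deg)
  out <- rbind(lower, equator, upper)
  out <- data.frame(channel_id = sprintf("E%02d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  structure(out, radius_cm = radius_cm, class = c("electrode_layout",
                                                  "data.frame"))
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("Shell MEA electrode layout: %d electrodes, radius %.4g cm\n",
              nrow(x), attr(x, "radius_cm")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Regular latitude-longitude grid on the sphere
#'
#' Grid nodes are offset by half a step so no node falls on a pole, where
#' the longitude metric degenerates.
#'
#' @param n_lat,n_lon number of latitude rows and longitude columns.
#' @param radius_cm sphere radius, cm.
#' @return object of class \code{sphere_grid} with elements \code{lat}
#'   (length \code{n_lat}, radians, increasing), \code{lon} (length
#'   \code{n_lon}), \code{radius_cm}.
#' @export
sphere_grid <- function(n_lat = 64, n_lon = 128, radius_cm = 0.025) {
  stopifnot(n_lat >= 2, n_lon >= 2, radius_cm > 0)
  dlat <- pi / n_lat
  dlon <- 2 * pi / n_lon
  structure(list(
    lat = -pi / 2 + dlat / 2 + dlat * (seq_len(n_lat) - 1),
    lon = dlon * (seq_len(n_lon) - 1),
    radius_cm = radius_cm
  ), class = "sphere_grid")
}

#' Radius of the circle through three planar points
#'
#' Utility for measuring radius of curvature from three hand-picked points
#' on an image (e.g. the fold radius of a shell MEA in a time-lapse frame).
#'
#' @param p1,p2,p3 numeric length-2 vectors (x, y).
#' @return circumradius, in the unit of the coordinates.
#' @export
circumradius_3pt <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  stopifnot(length(p1) == 2, length(p2) == 2, length(p3) == 2)
  a <- sqrt(sum((p1 - p2)^2))
  b <- sqrt(sum((p2 - p3)^2))
  c <- sqrt(sum((p3 - p1)^2))
  # signed double area via cross product
  cross2 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
    (p2[2] - p1[2]) * (p3[1] - p1[1])
  if (abs(cross2) < 1e-12 * max(a, b, c)^2)
    stop("circumradius_3pt: points are (near-)collinear")
  a * b * c / (2 * abs(cross2))
}

# Orthographic projection shared by the calcium generator and the
# hemisphere-projection of 3D maps: pixel centres -> points on the visible
# hemisphere. View "upper" looks down the polar axis (+z), "lower" looks up.
# Returns per-pixel lat/lon (radians) and a disk mask; pixels outside the
# projected disk get NA coordinates.
orthographic_pixel_coords <- function(n_px, pixel_size_um, radius_cm,
                                      view = c("upper", "lower")) {
  view <- match.arg(view)
  radius_um <- radius_cm * 1e4
  # pixel centre coordinates, image centred on the sphere centre
  ax <- (seq_len(n_px) - (n_px + 1) / 2) * pixel_size_um
  x <- matrix(ax, n_px, n_px)        # column coordinate (image x)
  y <- matrix(ax, n_px, n_px, byrow = TRUE)
  rho2 <- x^2 + y^2
  inside <- rho2 <= radius_um^2
  z <- sqrt(pmax(radius_um^2 - rho2, 0))
  if (view == "lower") z <- -z
  lat <- asin(pmin(pmax(z / radius_um, -1), 1))
  lon <- atan2(y, x)
  lat[!inside] <- NA_real_
  lon[!inside] <- NA_real_
  list(lat = lat, lon = lon, inside = inside, x_um = x, y_um = y)
}
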