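#' Inverse-quadratic radial basis function weight
#'
#' \code{RBF(d) = 1 / (1 + (d / epsilon)^2)}: 1 at zero distance, strictly
#' decreasing, never underflows to exactly 0 for finite distances.
#'
#' @param d distance(s), >= 0.
#' @param epsilon shape parameter (> 0), same unit as \code{d}; controls
#'   the smoothness of the interpolated surface.
#' @return weight(s) in (0, 1].
#' @export
rbf_weight <- function(d, epsilon) {
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("rbf_weight: epsilon must be > 0")
  stopifnot(all(d >= 0))
  1 / (1 + (d / epsilon)^2)
}

#' Default RBF shape parameter for a layout
#'
#' Mean nearest-neighbour geodesic spacing of the electrodes: a scale at
#' which each electrode dominates its own neighbourhood while neighbours
#' still share information.
#'
#' @param layout an \code{\link{shell_layout}}.
#' @return epsilon in cm.
#' @export
default_epsilon <- function(layout) {
  r <- attr(layout, "radius_cm")
  n <- nrow(layout)
  dmat <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine(layout$lat[i], layout$lon[i], layout$lat[j], layout$lon[j], r))
  diag(dmat) <- Inf
  mean(apply(dmat, 1, min))
}

#' Interpolate LAT values at arbitrary points on the sphere
#'
#' Normalised inverse-quadratic RBF smoothing of the electrode LATs with
#' haversine distances:
#' \deqn{LAT(p) = \sum_i w_i LAT_i / \sum_i w_i,\quad
#'   w_i = RBF(d(p, p_i))}
#' The result is a convex combination of the node LATs, so every
#' interpolated value lies within their range.
#'
#' @param lat,lon query point coordinates, radians (vectorised).
#' @param layout an \code{\link{shell_layout}} (or any electrode subset).
#' @param node_lats finite LAT values, one per layout row, s.
#' @param epsilon RBF shape parameter, cm; default
#'   \code{\link{default_epsilon}} of the layout.
#' @return interpolated LAT(s), s.
#' @export
interpolate_lat <- function(lat, lon, layout, node_lats, epsilon = NULL) {
  stopifnot(inherits(layout, "electrode_layout"),
            length(node_lats) == nrow(layout))
  if (any(!is.finite(node_lats)))
    stop("interpolate_lat: all node LATs must be finite")
  if (is.null(epsilon)) epsilon <- default_epsilon(layout)
  r <- attr(layout, "radius_cm")
  # n_query x n_nodes distance matrix
  d <- outer(seq_along(lat), seq_len(nrow(layout)), function(i, j)
    haversine(lat[i], lon[i], layout$lat[j], layout$lon[j], r))
  w <- rbf_weight(d, epsilon)
  sw <- rowSums(w)
  if (any(sw == 0))
    stop("interpolate_lat: all RBF weights underflowed to zero")
  as.numeric((w %*% node_lats) / sw)
}

#' Build a 3D isochrone map on a spherical grid
#'
#' Evaluates \code{\link{interpolate_lat}} at every grid node.
#'
#' @param layout an \code{\link{shell_layout}}.
#' @param node_lats per-electrode LATs, s (e.g. mean relative latencies
#'   from a \code{lat_table}).
#' @param grid a \code{\link{sphere_grid}}; default 64 x 128 at the layout
#'   radius.
#' @param epsilon RBF shape parameter, cm.
#' @return object of class \code{isochrone_map3d}: list with \code{grid},
#'   \code{values} (n_lat x n_lon matrix, s), \code{layout},
#'   \code{node_lats}, \code{epsilon}.
#' @export
build_isochrone <- function(layout, node_lats, grid = NULL, epsilon = NULL) {
  stopifnot(inherits(layout, "electrode_layout"))
  if (is.null(grid))
    grid <- sphere_grid(radius_cm = attr(layout, "radius_cm"))
  if (is.null(epsilon)) epsilon <- default_epsilon(layout)
  ll <- expand.grid(lat = grid$lat, lon = grid$lon)
  v <- interpolate_lat(ll$lat, ll$lon, layout, node_lats, epsilon)
  structure(list(grid = grid,
                 values = matrix(v, length(grid$lat), length(grid$lon)),
                 layout = layout, node_lats = node_lats, epsilon = epsilon),
            class = "isochrone_map3d")
}

#' Build an isochrone map directly from a scalar field on the grid
#'
#' Utility for mapping an analytically known activation-time field (e.g.
#' the generator's ground truth) onto the same container used by
#' \code{\link{cv_field}}.
#'
#' @param grid a \code{\link{sphere_grid}}.
#' @param fun function(lat, lon) returning activation times, s.
#' @return an \code{isochrone_map3d} (without layout/node information).
#' @export
isochrone_from_field <- function(grid, fun) {
  stopifnot(inherits(grid, "sphere_grid"))
  ll <- expand.grid(lat = grid$lat, lon = grid$lon)
  structure(list(grid = grid,
                 values = matrix(fun(ll$lat, ll$lon),
                                 length(grid$lat), length(grid$lon)),
                 layout = NULL, node_lats = NULL, epsilon = NULL),
            class = "isochrone_map3d")
}

#' @export
print.isochrone_map3d <- function(x, ...) {
  cat(sprintf("3D isochrone map: %d x %d grid, LAT range %.2f-%.2f ms\n",
              length(x$grid$lat), length(x$grid$lon),
              1e3 * min(x$values), 1e3 * max(x$values)))
  invisible(x)
}

#' @export
plot.isochrone_map3d <- function(x, ...) {
  graphics::image(x$grid$lon, x$grid$lat, t(x$values * 1e3),
                  xlab = "longitude (rad)", ylab = "latitude (rad)",
                  main = "LAT (ms)", ...)
  graphics::contour(x$grid$lon, x$grid$lat, t(x$values * 1e3), add = TRUE)
  invisible(x)
}

#' Conduction-velocity vector field from a 3D isochrone map
#'
#' Finite-difference gradients of the LAT field on the sphere:
#' \deqn{\nabla_x = (LAT_{east} - LAT_{west}) / (2 \Delta d_{east}),\quad
#'       \nabla_y = (LAT_{north} - LAT_{south}) / (2 \Delta d_{north})}
#' with local arc lengths \eqn{\Delta d_{east} = r\cos\phi\,\Delta\lambda}
#' (the metric factor \eqn{\cos\phi} corrects east-west spacing away from
#' the equator; disable with \code{metric_correction = FALSE}) and
#' \eqn{\Delta d_{north} = r\,\Delta\phi}. Longitude wraps periodically;
#' the top and bottom latitude rows use one-sided differences. Direction
#' is the normalised gradient and speed its inverse magnitude; nodes with
#' gradient magnitude below \code{grad_tol} are masked invalid.
#'
#' @param map an \code{\link{build_isochrone}} result.
#' @param grad_tol gradient-magnitude tolerance, s/cm; default
#'   \code{1e-3 / (pi * r)} (a 1 ms spread across a hemisphere).
#' @param metric_correction apply the \eqn{\cos\phi} east-west arc-length
#'   factor (default TRUE).
#' @return object of class \code{cv_field}: list with \code{grid},
#'   \code{dir_east}, \code{dir_north} (unit-vector components),
#'   \code{speed} (cm/s), \code{valid} (logical matrix), \code{grad_east},
#'   \code{grad_north} (s/cm).
#' @export
cv_field <- function(map, grad_tol = NULL, metric_correction = TRUE) {
  stopifnot(inherits(map, "isochrone_map3d"))
  g <- map$grid
  n_lat <- length(g$lat); n_lon <- length(g$lon)
  if (n_lat < 3 || n_lon < 3) stop("cv_field: grid must be at least 3 x 3")
  r <- g$radius_cm
  if (is.null(grad_tol)) grad_tol <- 1e-3 / (pi * r)
  v <- map$values
  dlon <- g$lon[2] - g$lon[1]
  dlat <- g$lat[2] - g$lat[1]

  # east-west: periodic wrap in longitude
  east <- v[, c(2:n_lon, 1)]
  west <- v[, c(n_lon, 1:(n_lon - 1))]
  cosphi <- if (metric_correction) cos(g$lat) else rep(1, n_lat)
  grad_east <- (east - west) / (2 * r * cosphi * dlon)

  # north-south: central differences, one-sided at boundary rows
  north <- v[c(2:n_lat, n_lat), ]
  south <- v[c(1, 1:(n_lat - 1)), ]
  denom <- rep(2 * r * dlat, n_lat)
  denom[c(1, n_lat)] <- r * dlat     # one-sided at the first/last row
  grad_north <- (north - south) / denom

  gmag <- sqrt(grad_east^2 + grad_north^2)
  valid <- gmag > grad_tol
  if (!any(valid))
    warning("cv_field: all nodes below gradient tolerance (constant map?)")
  dir_east <- ifelse(valid, grad_east / gmag, NA_real_)
  dir_north <- ifelse(valid, grad_north / gmag, NA_real_)
  speed <- ifelse(valid, 1 / gmag, NA_real_)
  structure(list(grid = g, dir_east = dir_east, dir_north = dir_north,
                 speed = speed, valid = valid, grad_east = grad_east,
                 grad_north = grad_north),
            class = "cv_field")
}

#' @export
print.cv_field <- function(x, ...) {
  sp <- x$speed[x$valid]
  cat(sprintf(
    "CV field: %d x %d grid, %d valid nodes; speed median %.3g cm/s (IQR %.3g-%.3g)\n",
    length(x$grid$lat), length(x$grid$lon), sum(x$valid),
    stats::median(sp), stats::quantile(sp, 0.25), stats::quantile(sp, 0.75)))
  invisible(x)
}

#' @export
summary.cv_field <- function(object, ...) {
  sp <- object$speed[object$valid]
  c(n_valid = sum(object$valid), mean = mean(sp),
    median = stats::median(sp), sd = stats::sd(sp))
}

#' Write an isochrone map (and optional CV field) as legacy ASCII VTK
#'
#' Emits a POLYDATA sphere mesh (one point per grid node, quad cells with
#' periodic longitude wrap) with point scalars \code{LAT} and, when a CV
#' field on the same grid is given, point vectors \code{CV} expressed in
#' 3D Cartesian components tangent to the sphere.
#'
#' @param map an \code{isochrone_map3d}.
#' @param path output file path.
#' @param cv optional \code{cv_field} on the same grid.
#' @return \code{path}, invisibly.
#' @export
export_vtk <- function(map, path, cv = NULL) {
  stopifnot(inherits(map, "isochrone_map3d"))
  g <- map$grid
  n_lat <- length(g$lat); n_lon <- length(g$lon)
  ll <- expand.grid(lat = g$lat, lon = g$lon)   # column-major like values
  r <- g$radius_cm
  px <- r * cos(ll$lat) * cos(ll$lon)
  py <- r * cos(ll$lat) * sin(ll$lon)
  pz <- r * sin(ll$lat)
  n_pts <- n_lat * n_lon
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "shellmea isochrone map", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", n_pts)), con)
  write(t(cbind(px, py, pz)), con, ncolumns = 3)
  # quads between adjacent lat rows, wrapping in longitude
  idx <- function(i, j) (j - 1) * n_lat + (i - 1)  # 0-based point id
  quads <- matrix(0L, nrow = (n_lat - 1) * n_lon, ncol = 4)
  k <- 1
  for (j in seq_len(n_lon)) {
    jn <- if (j == n_lon) 1L else j + 1L
    for (i in seq_len(n_lat - 1)) {
      quads[k, ] <- c(idx(i, j), idx(i, jn), idx(i + 1, jn), idx(i + 1, j))
      k <- k + 1
    }
  }
  writeLines(sprintf("POLYGONS %d %d", nrow(quads), nrow(quads) * 5), con)
  write(t(cbind(4L, quads)), con, ncolumns = 5)
  writeLines(c(sprintf("POINT_DATA %d", n_pts),
               "SCALARS LAT float 1", "LOOKUP_TABLE default"), con)
  write(as.vector(map$values), con, ncolumns = 9)
  if (!is.null(cv)) {
    stopifnot(inherits(cv, "cv_field"),
              identical(dim(cv$speed), dim(map$values)))
    # tangent basis: east = (-sin l, cos l, 0),
    # north = (-sin phi cos l, -sin phi sin l, cos phi)
    de <- as.vector(cv$dir_east); dn <- as.vector(cv$dir_north)
    de[is.na(de)] <- 0; dn[is.na(dn)] <- 0
    vx <- de * (-sin(ll$lon)) + dn * (-sin(ll$lat) * cos(ll$lon))
    vy <- de * cos(ll$lon) + dn * (-sin(ll$lat) * sin(ll$lon))
    vz <- dn * cos(ll$lat)
    writeLines("VECTORS CV float", con)
    write(t(cbind(vx, vy, vz)), con, ncolumns = 3)
  }
  invisible(path)
}

#' Read back a legacy VTK file written by \code{\link{export_vtk}}
#'
#' Minimal reader for round-trip checks: returns points, the LAT scalars
#' and the CV vectors (when present).
#'
#' @param path VTK file path.
#' @return list with \code{points} (n x 3), \code{lat} (vector),
#'   \code{cv} (n x 3 matrix or NULL).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  grab <- function(after, n_values) {
    vals <- numeric(0)
    i <- after + 1
    while (length(vals) < n_values && i <= length(lines)) {
      vals <- c(vals, scan(text = lines[i], quiet = TRUE))
      i <- i + 1
    }
    vals
  }
  ip <- grep("^POINTS", lines)
  n_pts <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  pts <- matrix(grab(ip, 3 * n_pts), ncol = 3, byrow = TRUE)
  is <- grep("^SCALARS LAT", lines)
  lat <- grab(is + 1, n_pts)   # skip LOOKUP_TABLE line
  iv <- grep("^VECTORS CV", lines)
  cv <- if (length(iv) == 1)
    matrix(grab(iv, 3 * n_pts), ncol = 3, byrow = TRUE) else NULL
  list(points = pts, lat = lat, cv = cv)
}
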