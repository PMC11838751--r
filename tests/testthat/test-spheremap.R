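# Independent direct evaluation of the normalised inverse-quadratic
# interpolation, coded as a plain double loop (oracle for the vectorised
# implementation).
interp_oracle <- function(qlat, qlon, elat, elon, r, vals, eps) {
  out <- numeric(length(qlat))
  for (q in seq_along(qlat)) {
    num <- 0; den <- 0
    for (i in seq_along(elat)) {
      a <- sin((elat[i] - qlat[q]) / 2)^2 +
        cos(qlat[q]) * cos(elat[i]) * sin((elon[i] - qlon[q]) / 2)^2
      d <- 2 * r * asin(sqrt(min(max(a, 0), 1)))
      w <- 1 / (1 + (d / eps)^2)
      num <- num + w * vals[i]
      den <- den + w
    }
    out[q] <- num / den
  }
  out
}

test_that("inverse-quadratic RBF weights match their closed form", {
  expect_equal(rbf_weight(0, 1), 1)
  expect_equal(rbf_weight(2, 2), 0.5)
  expect_equal(rbf_weight(3, 1), 0.1)
  d <- seq(0, 1, by = 0.01)
  expect_true(all(diff(rbf_weight(d, 0.3)) < 0))
  expect_error(rbf_weight(1, -1), "epsilon")
})

test_that("vectorised interpolation matches the brute-force oracle", {
  lay <- fixture_layout()
  r <- attr(lay, "radius_cm")
  set.seed(31)
  vals <- runif(16, 0, 0.015)
  eps <- default_epsilon(lay)
  qlat <- runif(1000, -pi / 2, pi / 2)
  qlon <- runif(1000, 0, 2 * pi)
  ours <- interpolate_lat(qlat, qlon, lay, vals, eps)
  ref <- interp_oracle(qlat, qlon, lay$lat, lay$lon, r, vals, eps)
  expect_lt(max(abs(ours - ref)), 1e-12)
  # convex-combination bound
  expect_true(all(ours >= min(vals) - 1e-15 & ours <= max(vals) + 1e-15))
})

test_that("interpolation respects symmetry, constants and rotation", {
  lay <- fixture_layout()
  # constant node LATs -> constant field
  out <- interpolate_lat(c(0.3, -1.2), c(0.1, 4), lay, rep(7e-3, 16))
  expect_equal(out, rep(7e-3, 2), tolerance = 1e-15)

  # two equidistant near nodes with all others much farther: as
  # epsilon -> 0 their mean dominates (weights ~ 1/d^2)
  toy <- data.frame(channel_id = sprintf("T%02d", 1:16),
                    lat = c(0, 0, rep(0.05 * (1:14 - 7.5), 1)),
                    lon = c(0.01, -0.01, rep(pi, 14)))
  toy <- structure(toy, radius_cm = 1,
                   class = c("electrode_layout", "data.frame"))
  vals <- c(1e-3, 3e-3, runif(14, 0, 0.02))
  mid <- interpolate_lat(0, 0, toy, vals, epsilon = 1e-5)
  expect_equal(mid, (1e-3 + 3e-3) / 2, tolerance = 1e-3)

  # equivariance under rotation about the polar axis
  set.seed(5)
  vals2 <- runif(16, 0, 0.01)
  delta <- 0.7
  lay_rot <- lay; lay_rot$lon <- lay$lon + delta
  attr(lay_rot, "radius_cm") <- attr(lay, "radius_cm")
  q <- cbind(runif(50, -pi / 2, pi / 2), runif(50, 0, 2 * pi))
  a <- interpolate_lat(q[, 1], q[, 2], lay, vals2, 0.01)
  b <- interpolate_lat(q[, 1], q[, 2] + delta, lay_rot, vals2, 0.01)
  expect_equal(a, b, tolerance = 1e-12)

  # weight concentration: at electrode positions a small epsilon recovers
  # the node value
  near <- interpolate_lat(lay$lat, lay$lon, lay, vals2,
                          epsilon = attr(lay, "radius_cm") / 1000)
  expect_equal(near, vals2, tolerance = 1e-4)
})

test_that("isochrone maps bound their node values and locate the origin", {
  lay <- fixture_layout()
  g <- sphere_grid(32, 64, attr(lay, "radius_cm"))
  # random node LATs, convexity at every node (many trials, vectorised)
  set.seed(17)
  for (k in 1:20) {
    vals <- runif(16, 0, 0.02)
    iso <- build_isochrone(lay, vals, g)
    expect_true(all(iso$values >= min(vals) & iso$values <= max(vals)))
  }
  # focal wave: map minimum within one ring spacing (45 deg) of the origin
  mod <- wavefront_model()
  tl <- true_activation_time(lay$lat, lay$lon, mod)
  iso <- build_isochrone(lay, tl, g)
  k <- which(iso$values == min(iso$values), arr.ind = TRUE)[1, ]
  ang <- haversine(g$lat[k[1]], g$lon[k[2]], mod$origin_lat, mod$origin_lon,
                   1)
  expect_lt(ang, 45 * pi / 180)
})

test_that("CV fields recover a linear activation field", {
  # T increasing linearly with equatorial arc length: speed v eastward on
  # the near-equatorial patch (metric factor cos(lat) ~ 1 there)
  g <- sphere_grid(48, 96, 0.025)
  v <- 5
  iso <- isochrone_from_field(g, function(la, lo) 0.025 * lo / v)
  cv <- cv_field(iso)
  # evaluate away from poles and the longitude wrap seam
  rows <- which(abs(g$lat) < 0.1)
  cols <- which(g$lon > 0.5 & g$lon < 2 * pi - 0.5)
  sp <- cv$speed[rows, cols]
  de <- cv$dir_east[rows, cols]
  expect_lt(max(abs(sp - v) / v), 0.01)
  expect_true(all(de > 0.999))
  # constant map -> fully masked
  flat <- isochrone_from_field(g, function(la, lo) rep(2e-3, length(la)))
  expect_warning(cvf <- cv_field(flat), "constant|tolerance")
  expect_equal(sum(cvf$valid), 0)
})

test_that("focal-wave CV matches the generator ground truth", {
  mod <- wavefront_model()
  g <- sphere_grid(64, 128, mod$sphere_radius)
  iso <- isochrone_from_field(g, function(la, lo)
    true_activation_time(la, lo, mod))
  cv <- cv_field(iso)
  ll <- expand.grid(lat = g$lat, lon = g$lon)
  ang <- matrix(haversine(ll$lat, ll$lon, mod$origin_lat, mod$origin_lon, 1),
                64, 128)
  ok <- cv$valid & ang > 20 * pi / 180 & ang < pi - 20 * pi / 180
  sp <- cv$speed[ok]
  expect_lt(abs(stats::median(sp) - mod$speed) / mod$speed, 0.1)
  # flat speed map: coefficient of variation below 15%
  expect_lt(stats::sd(sp) / mean(sp), 0.15)
})

test_that("VTK export round-trips scalars and keeps CV tangent", {
  lay <- fixture_layout()
  g <- sphere_grid(16, 32, attr(lay, "radius_cm"))
  mod <- wavefront_model()
  iso <- build_isochrone(lay, true_activation_time(lay$lat, lay$lon, mod), g)
  cv <- cv_field(iso)
  path <- tempfile(fileext = ".vtk")
  export_vtk(iso, path, cv = cv)
  back <- read_vtk(path)
  expect_equal(nrow(back$points), 16 * 32)
  expect_equal(back$lat, as.vector(iso$values), tolerance = 1e-6)
  # vectors tangent to the sphere: dot with the radial direction ~ 0
  radial <- back$points / sqrt(rowSums(back$points^2))
  dots <- abs(rowSums(back$cv * radial))
  expect_lt(max(dots), 1e-5)
})
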