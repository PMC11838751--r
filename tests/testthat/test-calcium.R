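make_stack <- function(frames, frame_rate = 60, pixel_size_um = 5) {
  structure(frames, frame_rate = frame_rate, pixel_size_um = pixel_size_um,
            class = "frame_stack")
}

make_map <- function(lat, pixel_size_um = 25) {
  structure(list(lat = lat, valid = !is.na(lat),
                 pixel_size_um = pixel_size_um, frame_rate = 60),
            class = "pixel_lat_map")
}

test_that("masks exclude background and occluded pixels", {
  cfg <- calcium_config(n_px = 64, pixel_size_um = 10,
                        photon_noise_sigma = 0.02)
  occ <- matrix(FALSE, 64, 64); occ[28:36, 28:36] <- TRUE
  cfg$occlusion_mask <- occ
  mv <- simulate_calcium_movie(wavefront_model(), cfg, "upper", seed = 4)
  mask <- build_mask(mv$stack, occlusion = occ)
  truth_mask <- !is.na(mv$truth)
  iou <- sum(mask & truth_mask) / sum(mask | truth_mask)
  expect_gte(iou, 0.95)
  # all-flat movie -> documented error
  flat <- make_stack(array(0.5, c(10, 8, 8)))
  expect_error(build_mask(flat), "empty mask")
  # threshold 0 keeps the full (non-occluded) field of view
  m0 <- build_mask(mv$stack, threshold_frac = 0, occlusion = occ)
  expect_true(all(m0[!occ]))
})

test_that("half-max pixel LATs match step, ramp and generator truth", {
  # step rise at frame k -> LAT = between frames k-1 and k
  fr <- array(0, c(20, 5, 5)); fr[10:20, , ] <- 1
  st <- make_stack(fr)
  pm <- pixel_lat(st, matrix(TRUE, 5, 5), neighborhood = 1)
  expect_true(all(abs(pm$lat - (8.5 / 60)) < 0.5 / 60))

  # linear ramp from 0 to 1 over 60 frames -> half-max at the middle
  ramp <- array(rep(seq(0, 1, length.out = 61), 25), c(61, 5, 5))
  pm2 <- pixel_lat(make_stack(ramp), matrix(TRUE, 5, 5), neighborhood = 1,
                   baseline_prob = 0)
  expect_equal(pm2$lat[3, 3], 0.5, tolerance = 0.02)

  # sigmoidal generator movie: error under one frame period
  cfg <- calcium_config(n_px = 48, pixel_size_um = 12,
                        photon_noise_sigma = 0.01)
  mv <- simulate_calcium_movie(wavefront_model(), cfg, "lower", seed = 6)
  mask <- build_mask(mv$stack)
  pm3 <- pixel_lat(mv$stack, mask)
  err <- abs(pm3$lat - mv$truth)
  expect_lt(stats::quantile(err, 0.99, na.rm = TRUE), 1 / 60)
  # gain/offset invariance of the half-max rule
  st2 <- make_stack(mv$stack * 3.7 + 12, 60, 12)
  pm4 <- pixel_lat(st2, mask)
  expect_equal(pm4$lat, pm3$lat, tolerance = 1e-9)
})

test_that("max pooling equals the brute-force window maximum", {
  set.seed(8)
  lat <- matrix(runif(23 * 17), 23, 17)
  lat[sample(length(lat), 40)] <- NA
  pooled <- pool_lat(make_map(lat, 5), window = 5)
  expect_equal(dim(pooled$lat), c(ceiling(23 / 5), ceiling(17 / 5)))
  expect_equal(pooled$pixel_size_um, 25)
  for (i in seq_len(nrow(pooled$lat))) {
    for (j in seq_len(ncol(pooled$lat))) {
      ri <- ((i - 1) * 5 + 1):min(i * 5, 23)
      cj <- ((j - 1) * 5 + 1):min(j * 5, 17)
      v <- lat[ri, cj]; v <- v[!is.na(v)]
      if (length(v) == 0) expect_true(is.na(pooled$lat[i, j]))
      else expect_equal(pooled$lat[i, j], max(v))
    }
  }
  # constant map -> constant pooled map
  cpool <- pool_lat(make_map(matrix(2, 10, 10)), 5)
  expect_true(all(cpool$lat == 2))
  # single late pixel dominates its window
  one <- matrix(0, 5, 5); one[2, 3] <- 9
  expect_equal(pool_lat(make_map(one), 5)$lat[1, 1], 9)
})

test_that("quadratic smoothing is exact on model-class inputs", {
  nx <- 21
  xs <- matrix(seq_len(nx), nx, nx)
  ys <- matrix(seq_len(nx), nx, nx, byrow = TRUE)
  # exactly quadratic input: zero residual, value reproduced
  quad <- 0.3 + 0.02 * xs - 0.01 * ys + 2e-3 * xs^2 - 1e-3 * xs * ys +
    5e-4 * ys^2
  sm <- smooth_lat(make_map(quad, 10), window_um = 100)
  expect_equal(sm$map$lat, quad, tolerance = 1e-9)
  expect_lt(max(sm$residual_rms, na.rm = TRUE), 1e-9)
  # constant input: a = c, higher terms 0
  smc <- smooth_lat(make_map(matrix(4, 15, 15), 10), window_um = 100)
  expect_equal(smc$map$lat, matrix(4, 15, 15), tolerance = 1e-12)
  ctr <- smc$coeffs[8, 8, ]
  expect_equal(ctr, c(4, 0, 0, 0, 0, 0), tolerance = 1e-10)
  # planar input T = alpha x: gradient coefficient recovered
  alpha <- 0.07
  plane <- alpha * xs
  smp <- smooth_lat(make_map(plane, 10), window_um = 100)
  expect_equal(smp$map$lat, plane, tolerance = 1e-9)
  expect_equal(smp$coeffs[11, 11, 2], alpha, tolerance = 1e-9)
  expect_lt(max(abs(smp$coeffs[11, 11, 3:6])), 1e-9)
})

test_that("planar CV recovers speed and scales with pixel size", {
  # T = x / v with v = 2.5 cm/s
  nx <- 31; px_um <- 20
  xs <- matrix(seq_len(nx), nx, nx)
  tmap <- xs * px_um * 1e-4 / 2.5
  cv <- cv_2d(make_map(tmap, px_um))
  sp <- cv$speed[cv$valid]
  expect_equal(mean(sp), 2.5, tolerance = 1e-9)
  expect_true(all(cv$dir_x[cv$valid] > 0.999))
  # constant map -> all pixels masked
  cvc <- cv_2d(make_map(matrix(1, 10, 10), px_um))
  expect_equal(sum(cvc$valid), 0)
  # doubling the pixel size halves the gradient, doubling the speed
  cv2 <- cv_2d(make_map(tmap, px_um), pixel_size_um = 2 * px_um)
  expect_equal(mean(cv2$speed[cv2$valid]), 5, tolerance = 1e-9)
})

test_that("the full calcium pipeline recovers a planar wave", {
  cfg <- calcium_config(photon_noise_sigma = 0.02)
  pw <- simulate_planar_movie(2.5, cfg, seed = 2)
  res <- calcium_pipeline(pw$stack)
  err <- abs(res$pixel_map$lat - pw$truth)
  expect_lt(mean(err, na.rm = TRUE), 1 / 60)
  sp <- res$cv$speed[res$cv$valid]
  expect_lt(abs(mean(sp) - 2.5) / 2.5, 0.15)
})
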