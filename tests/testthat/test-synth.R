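test_that("true activation time follows geodesic distance / speed", {
  mod <- wavefront_model(origin_lat = 0.2, origin_lon = 1.0, speed = 5,
                         sphere_radius = 0.025)
  # origin activates at 0
  expect_equal(true_activation_time(0.2, 1.0, mod), 0)
  # antipode: pi * r / v
  expect_equal(true_activation_time(-0.2, 1.0 + pi, mod), pi * 0.025 / 5,
               tolerance = 1e-12)
  # equidistant points activate simultaneously (symmetric longitudes)
  t1 <- true_activation_time(0.2, 1.3, mod)
  t2 <- true_activation_time(0.2, 0.7, mod)
  expect_equal(t1, t2, tolerance = 1e-12)
  # monotone in geodesic distance
  d <- seq(0, pi * 0.025, length.out = 20)
  lats <- true_activation_time(0.2 + d / 0.025, 1.0, mod)
  expect_true(all(diff(lats) >= -1e-15))
  # later beats offset by the beat period
  expect_equal(true_activation_time(0.2, 1.0, mod, beat = 3),
               2 * mod$beat_period)
  expect_error(true_activation_time(NaN, 0, mod), "finite")
})

test_that("waveform morphology progresses negative -> biphasic -> positive", {
  tmpl <- waveform_template()
  t <- seq(-0.02, 0.02, by = 1e-5)
  w0 <- shellmea:::template_waveform
  at_origin <- w0(t, tmpl, 0)
  mid <- w0(t, tmpl, 0.5)
  distal <- w0(t, tmpl, 1)
  # origin: purely negative depolarisation deflection
  expect_lte(max(at_origin), 1e-9)
  # mid-path: genuinely biphasic
  expect_gt(max(mid), 0.3 * tmpl$depol_amplitude / 2)
  expect_lt(min(mid), -0.3 * tmpl$depol_amplitude / 2)
  # distal: dominant positive deflection
  expect_gt(max(distal), -2 * min(distal))
  # balance is monotone in the activated fraction
  f <- seq(0, 1, by = 0.1)
  expect_true(all(diff(biphasic_balance(f)) > 0))
  # steepest negative slope sits at t = 0 for every morphology
  for (fr in c(0, 0.25, 0.5, 0.75, 1)) {
    x <- w0(t, tmpl, fr)
    dx <- diff(x)
    expect_lt(abs(t[which.min(dx)] + 5e-6), 2e-5)
  }
})

test_that("simulated recordings honour the ground truth and determinism", {
  lay <- fixture_layout()
  mod <- wavefront_model(n_beats = 3)
  tmpl <- waveform_template()
  sim1 <- simulate_recording(lay, mod, tmpl,
                             noise_model(sigma_white = 5, seed = 42))
  sim2 <- simulate_recording(lay, mod, tmpl,
                             noise_model(sigma_white = 5, seed = 42))
  expect_identical(sim1$recording$signals, sim2$recording$signals)

  # ground-truth LATs equal the analytic activation times (oracle identity)
  tru <- truth_matrix(sim1$truth)
  expected <- sapply(1:3, function(b)
    0.5 + true_activation_time(lay$lat, lay$lon, mod, beat = b))
  expect_equal(tru, expected, tolerance = 1e-12, ignore_attr = TRUE)

  # max inter-electrode spread bounded by pi r / v
  spread <- max(tru[, 1]) - min(tru[, 1])
  expect_lte(spread, pi * 0.025 / 5 + 1e-12)

  # earliest electrode has a dominant negative deflection
  noiseless <- simulate_recording(lay, mod, tmpl, noise_model())
  first_ch <- which.min(tru[, 1])
  x <- noiseless$recording$signals[first_ch, ]
  expect_gt(-min(x), 1.5 * max(x))
  expect_error(simulate_recording(lay, mod, tmpl, noise_model(),
                                  duration = 0.5),
               "duration")
})

test_that("drug-effect factors rescale the generator parameters", {
  mod <- wavefront_model(beat_period = 2)   # 30 bpm baseline
  tmpl <- waveform_template(fpd_true = 0.300)
  same <- apply_drug_effect(mod, tmpl)
  expect_equal(same$model, mod)
  expect_equal(same$template, tmpl)
  d <- apply_drug_effect(mod, tmpl, rate_factor = 1.84,
                         amplitude_factor = 1.81, fpd_factor = 0.80,
                         speed_factor = 1.2)
  expect_equal(60 / d$model$beat_period, 30 * 1.84)      # 55.2 bpm
  expect_equal(d$template$fpd_true, 0.300 * 0.80)        # 240 ms
  expect_equal(d$template$depol_amplitude, tmpl$depol_amplitude * 1.81)
  expect_equal(d$model$speed, mod$speed * 1.2)
  expect_error(apply_drug_effect(mod, tmpl, rate_factor = 0), "factor")
})

test_that("calcium movies encode activation as half-max upstroke times", {
  cfg <- calcium_config(n_px = 32, pixel_size_um = 20)
  # near-infinite speed: all pixels activate together
  fast <- wavefront_model(speed = 1e6)
  mv <- simulate_calcium_movie(fast, cfg, "upper", seed = 1)
  tr <- mv$truth[!is.na(mv$truth)]
  expect_lt(diff(range(tr)), 1e-6)

  # planar wave: upstroke time linear in the propagation coordinate
  pw <- simulate_planar_movie(2.5, cfg)
  t0 <- pw$truth
  cols_valid <- which(colSums(!is.na(t0)) > 0)
  row_vals <- t0[, cols_valid[5]]
  x <- which(!is.na(row_vals))
  fitres <- stats::lm(row_vals[x] ~ x)
  expect_lt(max(abs(stats::residuals(fitres))), 1e-12)

  # occluded pixels carry no signal
  occ <- matrix(FALSE, 32, 32); occ[10:14, 10:14] <- TRUE
  cfg_occ <- calcium_config(n_px = 32, pixel_size_um = 20,
                            occlusion_mask = occ)
  mv2 <- simulate_calcium_movie(wavefront_model(), cfg_occ, "upper")
  expect_true(all(is.na(mv2$truth[occ])))
  expect_true(all(mv2$stack[, 12, 12] == 0))
  expect_error(
    simulate_calcium_movie(wavefront_model(),
                           calcium_config(n_px = 8, pixel_size_um = 5)),
    "too small")
})
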