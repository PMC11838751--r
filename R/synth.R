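#' Focal wavefront model on a spherical organoid
#'
#' Ground truth for the mapping pipeline: a single focal origin from which
#' activation expands as a constant-speed geodesic wavefront over the
#' organoid surface, repeating every \code{beat_period}. The activation
#' time of a surface point within a beat is its geodesic distance from the
#' origin divided by the conduction speed; the maximum single-beat latency
#' is therefore \eqn{\pi r / v} (origin to antipode).
#'
#' @param origin_lat,origin_lon focal origin, radians.
#' @param speed conduction speed, cm/s (> 0).
#' @param sphere_radius organoid radius, cm (> 0).
#' @param beat_period interbeat interval, s (> 0).
#' @param n_beats number of beats (>= 1).
#' @return object of class \code{wavefront_model}.
#' @export
wavefront_model <- function(origin_lat = -0.5734, origin_lon = 3.2322,
                            speed = 5,
                            sphere_radius = 0.025, beat_period = 1.25,
                            n_beats = 10) {
  stopifnot(is.finite(origin_lat), is.finite(origin_lon),
            speed > 0, sphere_radius > 0, beat_period > 0, n_beats >= 1)
  structure(list(origin_lat = origin_lat, origin_lon = origin_lon,
                 speed = speed, sphere_radius = sphere_radius,
                 beat_period = beat_period, n_beats = as.integer(n_beats)),
            class = "wavefront_model")
}

#' @export
print.wavefront_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Focal wavefront: origin (%.3f, %.3f) rad, v = %.3g cm/s, ",
    "r = %.3g cm\n  period %.3g s x %d beats; max latency %.2f ms\n"),
    x$origin_lat, x$origin_lon, x$speed, x$sphere_radius,
    x$beat_period, x$n_beats, 1e3 * pi * x$sphere_radius / x$speed))
  invisible(x)
}

#' True activation time of a point on the organoid surface
#'
#' @param lat,lon point coordinates, radians (vectorised).
#' @param model a \code{\link{wavefront_model}}.
#' @param beat beat index (1-based); later beats are offset by
#'   \code{beat_period}.
#' @return activation time(s) in seconds.
#' @export
true_activation_time <- function(lat, lon, model, beat = 1) {
  stopifnot(inherits(model, "wavefront_model"), beat >= 1)
  d <- haversine(lat, lon, model$origin_lat, model$origin_lon,
                 model$sphere_radius)
  d / model$speed + (beat - 1) * model$beat_period
}

# Fraction of the sphere surface already activated when the wavefront
# reaches geodesic distance d from the origin: the spherical-cap area
# fraction (1 - cos(d/r)) / 2. Drives the unipolar waveform morphology.
activated_fraction <- function(d, r) (1 - cos(d / r)) / 2

#' Unipolar field-potential waveform template
#'
#' Morphology model for the extracellular depolarisation complex: an
#' amplitude-weighted mixture of a positive Gaussian lobe centred at
#' \code{-sigma} and a negative lobe centred at \code{+sigma}, where
#' \code{sigma = depol_width / 4}. The mixture weight is the activated
#' surface fraction \code{f} at the electrode: \code{f = 0} (origin) gives
#' a purely negative wave, mid-path values give biphasic waves, and distal
#' electrodes (\code{f -> 1}) give predominantly positive waves — the
#' classic unipolar electrogram progression. The construction places the
#' steepest negative slope of the waveform exactly at the true activation
#' time for every \code{f}, so slope-based LAT is unbiased by morphology
#' while the amplitude extremum shifts by about \code{+/- sigma}.
#'
#' Repolarisation is a low, wide positive deflection centred
#' \code{fpd_true} after the activation time.
#'
#' @param depol_width total depolarisation complex width, s (~4 sigma).
#' @param depol_amplitude depolarisation lobe amplitude, uV.
#' @param fpd_true true field potential duration (LAT to repolarisation
#'   peak), s.
#' @param repol_amplitude repolarisation peak amplitude, uV.
#' @param repol_width repolarisation Gaussian sigma, s.
#' @return object of class \code{waveform_template}.
#' @export
waveform_template <- function(depol_width = 0.003, depol_amplitude = 100,
                              fpd_true = 0.300, repol_amplitude = 25,
                              repol_width = 0.030) {
  stopifnot(depol_width > 0, depol_amplitude > 0, fpd_true > 0,
            repol_amplitude >= 0, repol_width > 0)
  structure(list(depol_width = depol_width,
                 depol_amplitude = depol_amplitude,
                 fpd_true = fpd_true,
                 repol_amplitude = repol_amplitude,
                 repol_width = repol_width),
            class = "waveform_template")
}

#' Biphasic balance of the depolarisation complex
#'
#' Maps the activated surface fraction to the morphology balance in
#' [-1, 1]: -1 purely negative (origin), 0 symmetric biphasic, +1 purely
#' positive (distal). Monotone in \code{f}.
#'
#' @param f activated fraction in [0, 1].
#' @return balance in [-1, 1].
#' @export
biphasic_balance <- function(f) {
  stopifnot(all(f >= 0 & f <= 1))
  2 * f - 1
}

# Evaluate the depolarisation + repolarisation template at times t
# (seconds, relative to the activation time) for activated fraction f.
template_waveform <- function(t, template, f) {
  sig <- template$depol_width / 4
  g <- function(u) exp(-u^2 / (2 * sig^2))
  depol <- template$depol_amplitude *
    (f * g(t + sig) - (1 - f) * g(t - sig))
  repol <- template$repol_amplitude *
    exp(-(t - template$fpd_true)^2 / (2 * template$repol_width^2))
  depol + repol
}

#' Recording noise model
#'
#' White Gaussian noise plus a sinusoidal line-interference component.
#' With \code{sigma_white = 0} and \code{line_amplitude = 0} the recording
#' is noiseless. All randomness flows through \code{seed}; per-channel
#' noise uses derived sub-streams so channels are independent but jointly
#' reproducible.
#'
#' @param sigma_white white-noise standard deviation, uV (>= 0).
#' @param line_amplitude line-interference amplitude, uV (>= 0).
#' @param line_freq line frequency, Hz (default 60).
#' @param seed integer seed.
#' @return object of class \code{noise_model}.
#' @export
noise_model <- function(sigma_white = 0, line_amplitude = 0, line_freq = 60,
                        seed = 1L) {
  stopifnot(sigma_white >= 0, line_amplitude >= 0, line_freq > 0)
  structure(list(sigma_white = sigma_white, line_amplitude = line_amplitude,
                 line_freq = line_freq, seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a 16-channel shell MEA recording
#'
#' Generates per-electrode unipolar field potentials for a focal wavefront:
#' each channel contains one depolarisation complex per beat centred at
#' the electrode's true activation time, with morphology set by the
#' activated surface fraction at that electrode, plus a repolarisation
#' deflection at \code{fpd_true} after each activation, white noise and
#' optional line interference.
#'
#' @param layout an \code{\link{shell_layout}} electrode layout; its radius
#'   must match \code{model$sphere_radius}.
#' @param model a \code{\link{wavefront_model}}.
#' @param template a \code{\link{waveform_template}}.
#' @param noise a \code{\link{noise_model}}.
#' @param fs sampling rate, Hz (default 30000).
#' @param duration recording length, s; must cover at least one beat
#'   period. Default covers all beats plus padding.
#' @param first_beat_at time of the first beat's origin activation, s.
#' @param origin_jitter per-beat angular jitter of the focal origin,
#'   radians (sd of an isotropic wobble; default 0 = fixed origin). A
#'   wandering origin changes both the per-beat true LATs and, through
#'   the activated fraction, the per-beat waveform morphology — the
#'   beat-to-beat variability seen in real organoid recordings.
#' @return list with \code{recording} (a \code{mea_recording}) and
#'   \code{truth}, a data frame of (channel_id, beat, lat_true, fpd_true).
#' @export
simulate_recording <- function(layout, model, template,
                               noise = noise_model(), fs = 30000,
                               duration = NULL, first_beat_at = 0.5,
                               origin_jitter = 0) {
  stopifnot(inherits(layout, "electrode_layout"),
            inherits(model, "wavefront_model"),
            inherits(template, "waveform_template"),
            inherits(noise, "noise_model"))
  if (abs(attr(layout, "radius_cm") - model$sphere_radius) > 1e-12)
    stop("simulate_recording: layout radius and model sphere_radius differ")
  if (is.null(duration))
    duration <- first_beat_at + model$n_beats * model$beat_period + 0.5
  if (duration < model$beat_period)
    stop("simulate_recording: duration shorter than one beat period")
  # template frequency content: Gaussian sigma depol_width/4 -> essentially
  # band-limited below ~4/(2*pi*sigma) Hz; require fs above twice that
  sig <- template$depol_width / 4
  if (fs < 2 * (4 / (2 * pi * sig)))
    stop("simulate_recording: fs too low for template bandwidth")

  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  n_ch <- nrow(layout)
  beats <- seq_len(model$n_beats)

  # per-beat origin (optionally wandering)
  o_lat <- rep(model$origin_lat, model$n_beats)
  o_lon <- rep(model$origin_lon, model$n_beats)
  if (origin_jitter > 0) {
    set.seed((noise$seed * 1000L + 999L) %% .Machine$integer.max)
    o_lat <- pmin(pmax(o_lat + rnorm(model$n_beats, sd = origin_jitter),
                       -pi / 2), pi / 2)
    o_lon <- o_lon + rnorm(model$n_beats, sd = origin_jitter)
  }
  # channel x beat distances, latencies and activated fractions
  d <- outer(seq_len(n_ch), beats, function(i, b)
    haversine(layout$lat[i], layout$lon[i], o_lat[b], o_lon[b],
              model$sphere_radius))
  lat_mat <- first_beat_at + d / model$speed +
    matrix((beats - 1) * model$beat_period, n_ch, model$n_beats,
           byrow = TRUE)
  f_mat <- activated_fraction(d, model$sphere_radius)

  signals <- matrix(0, n_ch, n)
  truth <- vector("list", n_ch)
  support <- 6 * sig  # evaluate template only on +/- support around events
  for (i in seq_len(n_ch)) {
    ch <- numeric(n)
    lat_i <- lat_mat[i, ]
    for (b in beats) {
      lo <- max(1L, floor((lat_i[b] - support) * fs) + 1L)
      hi <- min(n, ceiling((lat_i[b] + template$fpd_true +
                              6 * template$repol_width) * fs) + 1L)
      idx <- lo:hi
      ch[idx] <- ch[idx] +
        template_waveform(t[idx] - lat_i[b], template, f_mat[i, b])
    }
    if (noise$sigma_white > 0 || noise$line_amplitude > 0) {
      # per-channel derived sub-stream
      set.seed((noise$seed * 1000L + i) %% .Machine$integer.max)
      if (noise$sigma_white > 0)
        ch <- ch + rnorm(n, sd = noise$sigma_white)
      if (noise$line_amplitude > 0)
        ch <- ch + noise$line_amplitude *
          sin(2 * pi * noise$line_freq * t + runif(1, 0, 2 * pi))
    }
    signals[i, ] <- ch
    truth[[i]] <- data.frame(channel_id = layout$channel_id[i],
                             beat = beats, lat_true = lat_i,
                             fpd_true = template$fpd_true,
                             stringsAsFactors = FALSE)
  }
  rec <- mea_recording(signals, fs = fs, channel_ids = layout$channel_id)
  list(recording = rec, truth = do.call(rbind, truth))
}

#' Apply multiplicative drug-effect factors to the generator
#'
#' Models a cardioactive compound as multiplicative changes to the true
#' beat rate, field-potential amplitude, FPD and conduction speed, e.g.
#' an isoproterenol-like positive chronotrope/inotrope as
#' \code{rate_factor = 1.84, amplitude_factor = 1.81, fpd_factor = 0.80}.
#'
#' @param model a \code{\link{wavefront_model}}.
#' @param template a \code{\link{waveform_template}}.
#' @param rate_factor,amplitude_factor,fpd_factor,speed_factor positive
#'   multiplicative factors; 1 leaves the parameter unchanged.
#' @return list with modified \code{model} and \code{template}.
#' @export
apply_drug_effect <- function(model, template, rate_factor = 1,
                              amplitude_factor = 1, fpd_factor = 1,
                              speed_factor = 1) {
  stopifnot(inherits(model, "wavefront_model"),
            inherits(template, "waveform_template"))
  if (any(c(rate_factor, amplitude_factor, fpd_factor, speed_factor) <= 0))
    stop("apply_drug_effect: factors must be > 0")
  model$beat_period <- model$beat_period / rate_factor
  model$speed <- model$speed * speed_factor
  template$depol_amplitude <- template$depol_amplitude * amplitude_factor
  template$repol_amplitude <- template$repol_amplitude * amplitude_factor
  template$fpd_true <- template$fpd_true * fpd_factor
  list(model = model, template = template)
}

#' Calcium-imaging generator configuration
#'
#' @param frame_rate frames per second (default 60).
#' @param pixel_size_um microns per pixel.
#' @param n_px image side length, pixels (square frames).
#' @param rise_time calcium-transient upstroke time constant, s; the
#'   fluorescence rise is logistic and crosses half-maximum exactly at the
#'   pixel's true activation time.
#' @param decay_time transient decay time constant, s.
#' @param photon_noise_sigma additive Gaussian noise sd, arbitrary units
#'   (signal amplitude is 1).
#' @param occlusion_mask optional logical matrix (\code{n_px x n_px});
#'   TRUE pixels are occluded (e.g. under a gold electrode) and carry no
#'   signal.
#' @return object of class \code{calcium_config}.
#' @export
calcium_config <- function(frame_rate = 60, pixel_size_um = 5, n_px = 128,
                           rise_time = 0.04, decay_time = 0.4,
                           photon_noise_sigma = 0,
                           occlusion_mask = NULL) {
  stopifnot(frame_rate > 0, pixel_size_um > 0, n_px >= 8,
            rise_time > 0, decay_time > 0, photon_noise_sigma >= 0)
  if (!is.null(occlusion_mask))
    stopifnot(is.logical(occlusion_mask),
              all(dim(occlusion_mask) == c(n_px, n_px)))
  structure(list(frame_rate = frame_rate, pixel_size_um = pixel_size_um,
                 n_px = n_px, rise_time = rise_time,
                 decay_time = decay_time,
                 photon_noise_sigma = photon_noise_sigma,
                 occlusion_mask = occlusion_mask),
            class = "calcium_config")
}

#' Simulate a calcium-imaging movie of one hemisphere
#'
#' Orthographically projects the visible hemisphere of the organoid onto
#' the image plane and gives every in-organoid pixel a fluorescence
#' transient whose logistic upstroke crosses half-maximum at the pixel's
#' true activation time (first beat), followed by an exponential decay.
#' Occluded pixels and background pixels carry baseline (plus noise) only.
#'
#' @param model a \code{\link{wavefront_model}}.
#' @param cfg a \code{\link{calcium_config}}.
#' @param view which hemisphere faces the camera, \code{"upper"} or
#'   \code{"lower"}.
#' @param duration movie length, s; default covers the slowest pixel's
#'   upstroke plus decay.
#' @param t_activation_offset time of the origin's activation within the
#'   movie, s.
#' @param seed integer seed for photon noise.
#' @return list with \code{stack} (class \code{frame_stack}: array
#'   t x h x w, plus frame_rate/pixel_size attributes) and \code{truth}
#'   (matrix of per-pixel true upstroke times, NA where no signal).
#' @export
simulate_calcium_movie <- function(model, cfg, view = c("upper", "lower"),
                                   duration = NULL,
                                   t_activation_offset = 0.2, seed = 1L) {
  view <- match.arg(view)
  stopifnot(inherits(model, "wavefront_model"),
            inherits(cfg, "calcium_config"))
  radius_um <- model$sphere_radius * 1e4
  if (cfg$n_px * cfg$pixel_size_um < 2 * radius_um)
    stop("simulate_calcium_movie: image too small for the projected organoid")
  pc <- orthographic_pixel_coords(cfg$n_px, cfg$pixel_size_um,
                                  model$sphere_radius, view)
  t0 <- matrix(NA_real_, cfg$n_px, cfg$n_px)
  ok <- pc$inside
  t0[ok] <- t_activation_offset +
    true_activation_time(pc$lat[ok], pc$lon[ok], model)
  if (!is.null(cfg$occlusion_mask)) t0[cfg$occlusion_mask] <- NA_real_

  if (is.null(duration))
    duration <- t_activation_offset + pi * model$sphere_radius / model$speed +
      4 * cfg$decay_time
  list(stack = movie_from_lat_image(t0, cfg, duration, seed), truth = t0)
}

#' Synthesise a fluorescence movie from a per-pixel activation-time image
#'
#' Core of the calcium-movie generator, exposed so arbitrary wavefront
#' geometries (e.g. an exactly planar wave) can be emulated: each pixel
#' with a finite activation time gets a logistic upstroke crossing
#' half-maximum exactly at that time, followed by an exponential decay
#' engaged after the upstroke; NA pixels stay at baseline. Optional
#' additive Gaussian photon noise.
#'
#' @param t0 matrix of per-pixel activation times, s (NA = no signal);
#'   must be \code{cfg$n_px} square.
#' @param cfg a \code{\link{calcium_config}}.
#' @param duration movie length, s.
#' @param seed integer seed for photon noise.
#' @return a \code{frame_stack}.
#' @export
movie_from_lat_image <- function(t0, cfg, duration, seed = 1L) {
  stopifnot(inherits(cfg, "calcium_config"),
            all(dim(t0) == c(cfg$n_px, cfg$n_px)))
  if (!is.null(cfg$occlusion_mask)) t0[cfg$occlusion_mask] <- NA_real_
  n_frames <- max(2L, ceiling(duration * cfg$frame_rate))
  tt <- (seq_len(n_frames) - 1) / cfg$frame_rate
  frames <- array(0, dim = c(n_frames, cfg$n_px, cfg$n_px))
  flat_t0 <- as.vector(t0)
  live <- which(!is.na(flat_t0))
  tau <- cfg$rise_time / 4  # logistic scale; 10-90% rise ~ rise_time
  for (k in seq_len(n_frames)) {
    fr <- matrix(0, cfg$n_px, cfg$n_px)
    dt <- tt[k] - flat_t0[live]
    up <- 1 / (1 + exp(-dt / tau))
    dec <- exp(-pmax(dt - 3 * cfg$rise_time, 0) / cfg$decay_time)
    fr[live] <- up * dec
    frames[k, , ] <- fr
  }
  if (cfg$photon_noise_sigma > 0) {
    set.seed(seed %% .Machine$integer.max)
    frames <- frames + rnorm(length(frames), sd = cfg$photon_noise_sigma)
  }
  structure(frames, frame_rate = cfg$frame_rate,
            pixel_size_um = cfg$pixel_size_um, class = "frame_stack")
}

#' Simulate a planar-wave calcium movie
#'
#' A wave travelling at constant speed along the image x axis across a
#' disk-shaped organoid footprint: activation time is linear in the
#' propagation coordinate, so the recovered 2D conduction velocity has a
#' known ground truth.
#'
#' @param speed wave speed, cm/s.
#' @param cfg a \code{\link{calcium_config}}.
#' @param t_activation_offset time at which the wave enters the disk, s.
#' @param seed noise seed.
#' @return list with \code{stack} and \code{truth} (per-pixel activation
#'   times, NA outside the disk).
#' @export
simulate_planar_movie <- function(speed, cfg, t_activation_offset = 0.2,
                                  seed = 1L) {
  stopifnot(speed > 0, inherits(cfg, "calcium_config"))
  ax <- (seq_len(cfg$n_px) - (cfg$n_px + 1) / 2) * cfg$pixel_size_um
  radius_um <- max(ax) * 0.95
  x <- matrix(ax, cfg$n_px, cfg$n_px)
  y <- matrix(ax, cfg$n_px, cfg$n_px, byrow = TRUE)
  inside <- x^2 + y^2 <= radius_um^2
  t0 <- matrix(NA_real_, cfg$n_px, cfg$n_px)
  t0[inside] <- t_activation_offset +
    (x[inside] - min(x[inside])) * 1e-4 / speed   # um -> cm
  duration <- max(t0, na.rm = TRUE) + 4 * cfg$decay_time
  list(stack = movie_from_lat_image(t0, cfg, duration, seed), truth = t0)
}
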