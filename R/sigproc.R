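#' Multichannel MEA recording container
#'
#' @param signals numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate, Hz.
#' @param channel_ids unique channel labels; default E01..Enn.
#' @param t0 time of the first sample, s.
#' @return object of class \code{mea_recording}.
#' @export
mea_recording <- function(signals, fs, channel_ids = NULL, t0 = 0) {
  signals <- as.matrix(signals)
  stopifnot(is.numeric(signals), fs > 0)
  if (is.null(channel_ids))
    channel_ids <- sprintf("E%02d", seq_len(nrow(signals)))
  if (anyDuplicated(channel_ids))
    stop("mea_recording: channel_ids must be unique")
  stopifnot(length(channel_ids) == nrow(signals))
  rownames(signals) <- channel_ids
  structure(list(signals = signals, fs = fs,
                 channel_ids = as.character(channel_ids), t0 = t0),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("MEA recording: %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs))
  invisible(x)
}

#' @export
plot.mea_recording <- function(x, channels = seq_len(min(4, nrow(x$signals))),
                               tlim = NULL, ...) {
  t <- x$t0 + (seq_len(ncol(x$signals)) - 1) / x$fs
  sel <- if (is.null(tlim)) rep(TRUE, length(t)) else t >= tlim[1] & t <= tlim[2]
  old <- graphics::par(mfrow = c(length(channels), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (i in channels)
    graphics::plot(t[sel], x$signals[i, sel], type = "l",
                   xlab = "time (s)", ylab = x$channel_ids[i], ...)
  invisible(x)
}

#' Filtering and downsampling configuration
#'
#' Defaults follow standard MEA practice for cardiac field potentials:
#' downsample 30 kHz to 10 kHz, 1000 Hz low-pass (100 Hz for recordings
#' with strong interference), 60 Hz notch, all zero-phase so activation
#' times are not shifted by filter group delay.
#'
#' @param lowpass_hz low-pass cutoff, Hz (default 1000; use 100 for noisy
#'   recordings).
#' @param notch_hz notch centre frequency, Hz, or NULL to disable.
#' @param notch_q notch quality factor.
#' @param downsample_to target sampling rate, Hz.
#' @param zero_phase logical; forward-backward filtering when TRUE.
#' @param order Butterworth low-pass order.
#' @return object of class \code{filter_config}.
#' @export
filter_config <- function(lowpass_hz = 1000, notch_hz = 60, notch_q = 30,
                          downsample_to = 10000, zero_phase = TRUE,
                          order = 4) {
  stopifnot(lowpass_hz > 0, downsample_to > 0, order >= 1)
  if (lowpass_hz >= downsample_to / 2)
    stop("filter_config: lowpass_hz must be below the output Nyquist rate")
  if (!is.null(notch_hz)) stopifnot(notch_hz > 0, notch_q > 0)
  structure(list(lowpass_hz = lowpass_hz, notch_hz = notch_hz,
                 notch_q = notch_q, downsample_to = downsample_to,
                 zero_phase = zero_phase, order = order),
            class = "filter_config")
}

# RBJ audio-EQ-cookbook notch biquad; returns list(b, a)
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

# Filter with odd-reflection padding at both ends so IIR startup
# transients (notably the high-Q notch, ringing ~Q/(pi f0) seconds) decay
# in the padding, not in the data.
apply_filter <- function(x, b, a, zero_phase, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1, 5000L)
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- if (zero_phase) {
    as.numeric(signal::filtfilt(signal::Arma(b = b, a = a), xp))
  } else {
    as.numeric(signal::filter(signal::Arma(b = b, a = a), xp))
  }
  y[(pad + 1):(pad + n)]
}

#' Preprocess a recording: anti-alias, downsample, low-pass, notch
#'
#' Anti-alias filtering (Butterworth at 0.8 x the output Nyquist rate)
#' precedes decimation; when the input rate is an integer multiple of the
#' target the signal is decimated by that factor, otherwise it is
#' resampled by linear interpolation onto the target time base. The
#' Butterworth low-pass and the IIR notch are then applied at the output
#' rate. With \code{zero_phase = TRUE} all filters run forward-backward,
#' so a band-limited pulse's extremum shifts by less than one output
#' sample.
#'
#' @param rec a \code{\link{mea_recording}}.
#' @param cfg a \code{\link{filter_config}}.
#' @return a preprocessed \code{mea_recording} at \code{cfg$downsample_to}.
#' @export
preprocess <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(rec, "mea_recording"), inherits(cfg, "filter_config"))
  if (rec$fs < cfg$downsample_to)
    stop("preprocess: recording rate below downsample target")
  fs_out <- cfg$downsample_to
  x <- rec$signals
  n_in <- ncol(x)

  if (rec$fs > fs_out) {
    aa <- signal::butter(4, 0.8 * (fs_out / 2) / (rec$fs / 2), "low")
    factor <- rec$fs / fs_out
    if (abs(factor - round(factor)) < 1e-9) {
      factor <- round(factor)
      idx <- seq(1, n_in, by = factor)
      y <- t(apply(x, 1, function(ch) {
        apply_filter(ch, aa$b, aa$a, cfg$zero_phase)[idx]
      }))
    } else {
      # non-integer ratio: anti-alias then linear interpolation resample
      t_in <- (seq_len(n_in) - 1) / rec$fs
      t_out <- seq(0, t_in[n_in], by = 1 / fs_out)
      y <- t(apply(x, 1, function(ch) {
        ch_f <- apply_filter(ch, aa$b, aa$a, cfg$zero_phase)
        stats::approx(t_in, ch_f, xout = t_out)$y
      }))
    }
  } else {
    y <- x
  }

  lp <- signal::butter(cfg$order, cfg$lowpass_hz / (fs_out / 2), "low")
  y <- t(apply(y, 1, apply_filter, b = lp$b, a = lp$a,
               zero_phase = cfg$zero_phase))
  if (!is.null(cfg$notch_hz)) {
    nb <- notch_biquad(cfg$notch_hz, fs_out, cfg$notch_q)
    y <- t(apply(y, 1, apply_filter, b = nb$b, a = nb$a,
                 zero_phase = cfg$zero_phase))
  }
  mea_recording(y, fs = fs_out, channel_ids = rec$channel_ids, t0 = rec$t0)
}

#' Signal-to-noise ratio of one channel
#'
#' SNR = amplitude / sigma_noise, where amplitude is the peak-to-peak
#' voltage over the union of the beat windows and sigma_noise the standard
#' deviation of the remaining (noise) samples.
#'
#' @param x numeric vector, one channel.
#' @param beat_windows list of integer vectors \code{c(start, end)}
#'   (sample indices, inclusive) marking signal segments.
#' @return list with \code{amplitude}, \code{sigma_noise}, \code{snr}.
#' @export
compute_snr <- function(x, beat_windows) {
  stopifnot(is.numeric(x), length(beat_windows) >= 1)
  in_beat <- rep(FALSE, length(x))
  for (w in beat_windows) {
    stopifnot(length(w) == 2, w[1] >= 1, w[2] <= length(x), w[1] <= w[2])
    in_beat[w[1]:w[2]] <- TRUE
  }
  if (!any(in_beat)) stop("compute_snr: empty beat windows")
  if (sum(!in_beat) < 100)
    stop("compute_snr: insufficient noise segment (< 100 samples)")
  amplitude <- max(x[in_beat]) - min(x[in_beat])
  sigma_noise <- stats::sd(x[!in_beat])
  if (sigma_noise == 0)
    stop("compute_snr: degenerate noise segment (sigma = 0)")
  list(amplitude = amplitude, sigma_noise = sigma_noise,
       snr = amplitude / sigma_noise)
}
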