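#' Nonlinear energy operator
#'
#' \code{NEO[x](n) = x(n)^2 - x(n-1) x(n+1)}, emphasising transient
#' high-frequency energy for event detection. Boundary samples are set
#' to 0.
#'
#' @param x numeric vector, length >= 3.
#' @return numeric vector of the same length.
#' @export
neo <- function(x) {
  n <- length(x)
  if (n < 3) stop("neo: signal must have length >= 3")
  out <- numeric(n)
  i <- 2:(n - 1)
  out[i] <- x[i]^2 - x[i - 1] * x[i + 1]
  out
}

#' Detect beats from an NEO trace
#'
#' The NEO trace is first smoothed with a short moving average (raw NEO of
#' broadband noise is heavy-tailed; smoothing makes the noise floor
#' near-Gaussian so a robust threshold is meaningful). Beats are
#' threshold exceedances above
#' \code{median + k * (MAD / 0.6745)} of the smoothed trace, with a small
#' peak-fraction floor so that in (near-)noiseless recordings, where the
#' robust scale collapses to zero, only genuine depolarisation bursts —
#' not low-energy repolarisation humps — are detected. Exceedance peaks
#' are kept greedily by NEO magnitude subject to the refractory period,
#' and returned as analysis windows clipped to the signal bounds.
#'
#' @param neo_signal NEO trace (from \code{\link{neo}}).
#' @param fs sampling rate, Hz.
#' @param threshold_k threshold multiplier (> 0), default 8.
#' @param refractory minimum beat separation, s, default 0.2.
#' @param window window extent around each NEO peak,
#'   \code{c(before, after)} in seconds, default 50 ms before / 150 ms
#'   after.
#' @param smooth_ms moving-average length for the NEO trace, ms.
#' @param peak_floor_frac threshold floor as a fraction of the smoothed
#'   NEO maximum.
#' @return list of integer windows \code{c(start, end)} (sample indices);
#'   empty list when nothing exceeds threshold.
#' @export
detect_beats <- function(neo_signal, fs, threshold_k = 8, refractory = 0.2,
                         window = c(0.05, 0.15), smooth_ms = 5,
                         peak_floor_frac = 0.05) {
  stopifnot(threshold_k > 0, refractory > 0, fs > 0)
  n <- length(neo_signal)
  if (refractory >= n / fs)
    stop("detect_beats: refractory period exceeds signal duration")
  w <- max(1L, round(smooth_ms / 1000 * fs))
  sm <- as.numeric(stats::filter(neo_signal, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- 0
  med <- stats::median(sm)
  scale <- stats::mad(sm, constant = 1) / 0.6745
  thr <- max(med + threshold_k * scale, peak_floor_frac * max(sm))
  if (thr <= 0) return(list())
  neo_signal <- sm
  above <- which(neo_signal > thr)
  if (length(above) == 0) return(list())
  # order candidate peaks by NEO magnitude, greedily enforce refractory
  ord <- above[order(neo_signal[above], decreasing = TRUE)]
  min_gap <- round(refractory * fs)
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  lapply(keep, function(i) {
    c(max(1L, i - round(window[1] * fs)),
      min(n, i + round(window[2] * fs)))
  })
}

#' Local activation time within a beat window
#'
#' Slope method: LAT is the time of the steepest negative slope
#' \code{Smax = min dx/dt} (central difference); amplitude method: LAT is
#' the time of the extremum of \code{|x|}. Ties are broken toward the
#' earliest sample.
#'
#' @param x windowed signal, length >= 3.
#' @param fs sampling rate, Hz.
#' @param method \code{"slope"} or \code{"amplitude"}.
#' @param t_start time of the first sample of the window, s.
#' @return list with \code{lat} (s) and \code{value} (Smax in uV/s for
#'   slope, the signed peak voltage in uV for amplitude).
#' @export
detect_lat <- function(x, fs, method = c("slope", "amplitude"),
                       t_start = 0) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3) stop("detect_lat: window must have length >= 3")
  if (method == "slope") {
    dx <- numeric(n)
    i <- 2:(n - 1)
    dx[i] <- (x[i + 1] - x[i - 1]) * fs / 2
    dx[c(1, n)] <- NA
    if (all(dx[i] == 0))
      stop("detect_lat: flat window (zero derivative everywhere)")
    k <- i[which.min(dx[i])]          # which.min takes the earliest tie
    list(lat = t_start + (k - 1) / fs, value = dx[k])
  } else {
    k <- which.max(abs(x))
    list(lat = t_start + (k - 1) / fs, value = x[k])
  }
}

#' Build a per-channel, per-beat LAT table from a recording
#'
#' Beats are detected on the summed NEO trace across channels (a robust
#' consensus of beat timing); within each beat window every channel's LAT
#' is extracted with \code{\link{detect_lat}}. Relative latencies are
#' computed per beat against the first-activating channel.
#'
#' @param rec a preprocessed \code{\link{mea_recording}}.
#' @param method LAT detection method, \code{"slope"} or
#'   \code{"amplitude"}.
#' @param threshold_k,refractory,window passed to
#'   \code{\link{detect_beats}}.
#' @return object of class \code{lat_table}: list with \code{lat} (matrix
#'   channels x beats, absolute seconds), \code{relative} (same shape,
#'   first-activating channel = 0 per beat), \code{mean_lat},
#'   \code{channel_ids}, \code{windows}, \code{method}, \code{fs}.
#' @export
build_lat_table <- function(rec, method = c("slope", "amplitude"),
                            threshold_k = 8, refractory = 0.2,
                            window = c(0.05, 0.15)) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "mea_recording"))
  neo_sum <- rowSums(sapply(seq_len(nrow(rec$signals)),
                            function(i) neo(rec$signals[i, ])))
  wins <- detect_beats(neo_sum, rec$fs, threshold_k, refractory, window)
  if (length(wins) == 0) stop("build_lat_table: no beats detected")
  n_ch <- nrow(rec$signals)
  lat <- matrix(NA_real_, n_ch, length(wins),
                dimnames = list(rec$channel_ids, NULL))
  for (b in seq_along(wins)) {
    w <- wins[[b]]
    for (i in seq_len(n_ch)) {
      res <- try(detect_lat(rec$signals[i, w[1]:w[2]], rec$fs, method,
                            t_start = rec$t0 + (w[1] - 1) / rec$fs),
                 silent = TRUE)
      if (!inherits(res, "try-error")) lat[i, b] <- res$lat
    }
  }
  relative <- sweep(lat, 2, apply(lat, 2, min, na.rm = TRUE))
  structure(list(lat = lat, relative = relative,
                 mean_lat = rowMeans(lat, na.rm = TRUE),
                 channel_ids = rec$channel_ids, windows = wins,
                 method = method, fs = rec$fs),
            class = "lat_table")
}

#' @export
print.lat_table <- function(x, ...) {
  cat(sprintf("LAT table (%s method): %d channels x %d beats\n",
              x$method, nrow(x$lat), ncol(x$lat)))
  rel <- sort(rowMeans(x$relative, na.rm = TRUE))
  cat("Mean relative latencies (ms):\n")
  print(round(rel * 1e3, 3))
  invisible(x)
}

#' Activation order and rank confusion matrix
#'
#' The reference activation order is the ranking of per-channel mean LATs.
#' For every beat where all channels were detected, each electrode's rank
#' within that beat is tallied into an electrode x rank confusion matrix;
#' accuracy is the fraction of (electrode, beat) pairs whose per-beat rank
#' equals the reference rank.
#'
#' @param lat_table a \code{\link{build_lat_table}} result.
#' @return object of class \code{order_confusion}: list with
#'   \code{confusion} (n_ch x n_ch counts, rows = electrodes ordered as in
#'   the table, columns = rank), \code{reference_rank}, \code{accuracy},
#'   \code{n_beats} (beats used).
#' @export
activation_order <- function(lat_table) {
  stopifnot(inherits(lat_table, "lat_table"))
  lat <- lat_table$lat
  complete <- colSums(is.na(lat)) == 0
  if (sum(complete) < 2)
    stop("activation_order: need >= 2 beats with all channels detected")
  if (any(!complete))
    message(sprintf("activation_order: excluding %d beat(s) with missing channels",
                    sum(!complete)))
  lat <- lat[, complete, drop = FALSE]
  n_ch <- nrow(lat)
  ref_rank <- rank(rowMeans(lat), ties.method = "first")
  confusion <- matrix(0L, n_ch, n_ch,
                      dimnames = list(rownames(lat), paste0("rank", 1:n_ch)))
  hits <- 0L
  for (b in seq_len(ncol(lat))) {
    rk <- rank(lat[, b], ties.method = "first")
    confusion[cbind(seq_len(n_ch), rk)] <- confusion[cbind(seq_len(n_ch), rk)] + 1L
    hits <- hits + sum(rk == ref_rank)
  }
  structure(list(confusion = confusion, reference_rank = ref_rank,
                 accuracy = hits / (n_ch * ncol(lat)),
                 n_beats = ncol(lat)),
            class = "order_confusion")
}

#' @export
print.order_confusion <- function(x, ...) {
  cat(sprintf("Activation-order confusion: %d beats, accuracy %.3f\n",
              x$n_beats, x$accuracy))
  invisible(x)
}
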