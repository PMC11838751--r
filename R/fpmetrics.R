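#' Beat rate from consecutive activation times
#'
#' @param lats sorted activation times of one channel, s (>= 2 values).
#' @return beat rate in bpm: \code{60 / mean(diff(lats))}.
#' @export
beat_rate <- function(lats) {
  if (length(lats) < 2)
    stop("beat_rate: need at least 2 activation times")
  60 / mean(diff(sort(lats)))
}

#' Field potential duration of one beat
#'
#' FPD is the time from the LAT to the first repolarisation peak, taken as
#' the dominant (largest \code{|x|}) extremum in the search interval
#' \code{(lat + blanking, search_end]} — the blanking period excludes the
#' depolarisation complex itself. A warning is raised when the extremum
#' falls on the interval boundary (likely truncated repolarisation).
#'
#' @param x signal segment containing the beat, uV.
#' @param lat activation time, s, on the same time base as \code{x}.
#' @param fs sampling rate, Hz.
#' @param t_start time of \code{x[1]}, s.
#' @param blanking dead time after the LAT, s (default 0.05).
#' @param search_end end of the search interval, s; default end of the
#'   segment.
#' @return list with \code{fpd} (s) and \code{peak} (signed voltage, uV).
#' @export
fpd <- function(x, lat, fs, t_start = 0, blanking = 0.05,
                search_end = NULL) {
  n <- length(x)
  t_end_seg <- t_start + (n - 1) / fs
  if (is.null(search_end)) search_end <- t_end_seg
  i0 <- ceiling((lat + blanking - t_start) * fs) + 1
  i1 <- floor((search_end - t_start) * fs) + 1
  i0 <- max(i0, 1); i1 <- min(i1, n)
  if (i0 >= i1)
    stop("fpd: empty search interval (lat + blanking, search_end]")
  seg <- x[i0:i1]
  k <- which.max(abs(seg))
  if (k == 1 || k == length(seg))
    warning("fpd: repolarisation extremum on search-interval boundary")
  t_peak <- t_start + (i0 + k - 2) / fs
  list(fpd = t_peak - lat, peak = seg[k])
}

#' Per-channel waveform metrics: amplitude, beat rate, FPD
#'
#' Amplitude is the peak-to-peak voltage within the beat windows (mean
#' over beats); beat rate comes from the interbeat intervals of the
#' channel's LATs; FPD is measured per beat with \code{\link{fpd}},
#' searching from the LAT to 50 ms before the next beat's LAT.
#'
#' @param rec a preprocessed \code{\link{mea_recording}}.
#' @param lat_table matching \code{\link{build_lat_table}} result.
#' @param blanking FPD blanking period, s.
#' @return object of class \code{waveform_metrics}: data frame with one
#'   row per channel (amplitude_uv, beat_rate_bpm, fpd_s, n_beats).
#' @export
waveform_metrics <- function(rec, lat_table, blanking = 0.05) {
  stopifnot(inherits(rec, "mea_recording"), inherits(lat_table, "lat_table"))
  n_ch <- nrow(rec$signals)
  out <- data.frame(channel_id = rec$channel_ids,
                    amplitude_uv = NA_real_, beat_rate_bpm = NA_real_,
                    fpd_s = NA_real_, n_beats = NA_integer_,
                    stringsAsFactors = FALSE)
  wins <- lat_table$windows
  for (i in seq_len(n_ch)) {
    x <- rec$signals[i, ]
    lats <- lat_table$lat[i, ]
    lats <- lats[!is.na(lats)]
    if (length(lats) < 2) next
    amp <- vapply(wins, function(w) {
      seg <- x[w[1]:w[2]]
      max(seg) - min(seg)
    }, numeric(1))
    fpds <- rep(NA_real_, length(lats))
    ord <- order(lats)
    lats_s <- lats[ord]
    for (b in seq_along(lats_s)) {
      s_end <- if (b < length(lats_s)) lats_s[b + 1] - 0.05 else
        lats_s[b] + min(diff(lats_s)) - 0.05
      i0 <- max(1L, floor((lats_s[b] - rec$t0) * rec$fs) + 1L)
      i1 <- min(ncol(rec$signals),
                ceiling((s_end - rec$t0) * rec$fs) + 1L)
      if (i1 - i0 < 3) next
      res <- try(fpd(x[i0:i1], lats_s[b], rec$fs,
                     t_start = rec$t0 + (i0 - 1) / rec$fs,
                     blanking = blanking, search_end = s_end),
                 silent = TRUE)
      if (!inherits(res, "try-error")) fpds[b] <- res$fpd
    }
    out$amplitude_uv[i] <- mean(amp)
    out$beat_rate_bpm[i] <- beat_rate(lats_s)
    out$fpd_s[i] <- mean(fpds, na.rm = TRUE)
    out$n_beats[i] <- length(lats_s)
  }
  class(out) <- c("waveform_metrics", "data.frame")
  out
}

#' Drug-response summary: percent change of waveform metrics
#'
#' Compares per-channel waveform metrics before and after treatment.
#' Channels present in only one recording are excluded (with a message).
#' Percent change is \code{(post - pre) / pre * 100}; the summary reports
#' cross-channel mean +/- SEM and a paired t-test p-value per metric.
#'
#' @param pre,post \code{\link{waveform_metrics}} for the baseline and
#'   treated recordings (identical processing configuration assumed).
#' @return object of class \code{drug_response}: list with
#'   \code{per_channel} (data frame of percent changes) and
#'   \code{summary} (metric, mean_pct, sem_pct, p_value).
#' @export
drug_response <- function(pre, post) {
  stopifnot(inherits(pre, "waveform_metrics"),
            inherits(post, "waveform_metrics"))
  common <- intersect(pre$channel_id, post$channel_id)
  dropped <- setdiff(union(pre$channel_id, post$channel_id), common)
  if (length(dropped) > 0)
    message("drug_response: excluding channels missing in one recording: ",
            paste(dropped, collapse = ", "))
  a <- pre[match(common, pre$channel_id), ]
  b <- post[match(common, post$channel_id), ]
  metrics <- c("amplitude_uv", "beat_rate_bpm", "fpd_s")
  pct <- as.data.frame(lapply(metrics, function(m) {
    (b[[m]] - a[[m]]) / a[[m]] * 100
  }))
  names(pct) <- sub("_(uv|bpm|s)$", "_pct", metrics)
  per_channel <- data.frame(channel_id = common, pct,
                            stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(seq_along(metrics), function(j) {
    x <- pct[[j]]
    x <- x[is.finite(x)]
    p <- if (length(x) >= 2 && stats::sd(b[[metrics[j]]] - a[[metrics[j]]],
                                         na.rm = TRUE) > 0)
      stats::t.test(b[[metrics[j]]], a[[metrics[j]]], paired = TRUE)$p.value
    else NA_real_
    data.frame(metric = metrics[j], mean_pct = mean(x),
               sem_pct = stats::sd(x) / sqrt(length(x)), p_value = p,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_channel = per_channel, summary = summary),
            class = "drug_response")
}

#' @export
print.drug_response <- function(x, ...) {
  cat("Drug response (percent change, mean +/- SEM):\n")
  s <- x$summary
  for (j in seq_len(nrow(s)))
    cat(sprintf("  %-15s %+7.1f%% +/- %.1f (p = %.3g)\n", s$metric[j],
                s$mean_pct[j], s$sem_pct[j], s$p_value[j]))
  invisible(x)
}
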