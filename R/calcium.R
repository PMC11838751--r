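#' Build a signal mask for a calcium movie
#'
#' Excludes background and occluded pixels by per-pixel dynamic range:
#' a pixel is kept when its temporal range (max - min) exceeds
#' \code{threshold_frac} of the largest per-pixel range in the movie.
#' A known occlusion geometry (e.g. pixels under the gold electrodes)
#' can be excluded explicitly.
#'
#' @param stack a \code{frame_stack} (array t x h x w).
#' @param threshold_frac dynamic-range threshold as a fraction of the
#'   movie's maximum per-pixel range, in [0, 1); default 0.5.
#' @param occlusion optional logical h x w matrix of pixels to exclude.
#' @return logical h x w matrix (TRUE = signal pixel).
#' @export
build_mask <- function(stack, threshold_frac = 0.5, occlusion = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  rng <- apply(stack, c(2, 3), function(v) max(v) - min(v))
  mask <- rng > threshold_frac * max(rng)
  if (!is.null(occlusion)) {
    stopifnot(is.logical(occlusion), all(dim(occlusion) == dim(mask)))
    mask <- mask & !occlusion
  }
  if (!any(mask))
    stop("build_mask: empty mask (no pixel exceeds the dynamic-range threshold)")
  mask
}

# Local spatial mean over an odd k x k neighbourhood, per frame.
local_mean_stack <- function(stack, k) {
  if (k == 1) return(stack)
  n_t <- dim(stack)[1]; h <- dim(stack)[2]; w <- dim(stack)[3]
  half <- (k - 1) / 2
  out <- array(0, dim(stack))
  for (tt in seq_len(n_t)) {
    fr <- stack[tt, , ]
    # separable box filter with edge clipping via cumulative sums
    cs <- apply(rbind(0, fr), 2, cumsum)
    lo <- pmax(seq_len(h) - half, 1); hi <- pmin(seq_len(h) + half, h)
    fr2 <- (cs[hi + 1, ] - cs[lo, ]) / (hi - lo + 1)
    cs2 <- apply(cbind(0, fr2), 1, cumsum)  # transposed: w+1 x h
    lo2 <- pmax(seq_len(w) - half, 1); hi2 <- pmin(seq_len(w) + half, w)
    out[tt, , ] <- t((cs2[hi2 + 1, ] - cs2[lo2, ]) / (hi2 - lo2 + 1))
  }
  out
}

#' Per-pixel half-maximum activation times from a calcium movie
#'
#' For every masked-in pixel the trace is the local spatial mean over an
#' odd neighbourhood (default 3 x 3: the pixel and its surrounding
#' pixels). Baseline is a low percentile of the trace; the pixel LAT is
#' the first time the trace crosses baseline + 0.5 (max - baseline),
#' linearly interpolated between frames. Pixels whose trace never crosses
#' half-maximum are marked invalid.
#'
#' @param stack a \code{frame_stack}.
#' @param mask logical matrix from \code{\link{build_mask}}.
#' @param neighborhood odd neighbourhood side length (default 3).
#' @param baseline_prob baseline percentile of the trace (default 0.1).
#' @return object of class \code{pixel_lat_map}: list with \code{lat}
#'   (h x w matrix, s, NA where invalid), \code{valid},
#'   \code{pixel_size_um}, \code{frame_rate}.
#' @export
pixel_lat <- function(stack, mask, neighborhood = 3, baseline_prob = 0.1) {
  stopifnot(inherits(stack, "frame_stack"),
            neighborhood >= 1, neighborhood %% 2 == 1)
  sm <- local_mean_stack(stack, neighborhood)
  h <- dim(stack)[2]; w <- dim(stack)[3]
  fr <- attr(stack, "frame_rate")
  lat <- matrix(NA_real_, h, w)
  idx <- which(mask, arr.ind = TRUE)
  for (p in seq_len(nrow(idx))) {
    tr <- sm[, idx[p, 1], idx[p, 2]]
    base <- stats::quantile(tr, baseline_prob, names = FALSE)
    half <- base + 0.5 * (max(tr) - base)
    k <- which(tr >= half)[1]
    if (is.na(k)) next
    if (k == 1) {
      lat[idx[p, 1], idx[p, 2]] <- 0
    } else {
      # linear interpolation between frames k-1 and k
      frac <- (half - tr[k - 1]) / (tr[k] - tr[k - 1])
      lat[idx[p, 1], idx[p, 2]] <- (k - 2 + frac) / fr
    }
  }
  structure(list(lat = lat, valid = !is.na(lat),
                 pixel_size_um = attr(stack, "pixel_size_um"),
                 frame_rate = fr),
            class = "pixel_lat_map")
}

#' Max-pool a pixel LAT map
#'
#' Non-overlapping window maximum over valid pixels; windows containing
#' no valid pixel are invalid. Output dimensions are
#' \code{ceiling(input / window)}. Mean pooling is available as an
#' alternative downsampling rule.
#'
#' @param map a \code{\link{pixel_lat_map}}.
#' @param window pooling window side (default 5).
#' @param fun \code{"max"} (default) or \code{"mean"}.
#' @return a pooled \code{pixel_lat_map}; \code{pixel_size_um} scales by
#'   \code{window}.
#' @export
pool_lat <- function(map, window = 5, fun = c("max", "mean")) {
  fun <- match.arg(fun)
  stopifnot(inherits(map, "pixel_lat_map"), window >= 1)
  h <- nrow(map$lat); w <- ncol(map$lat)
  ho <- ceiling(h / window); wo <- ceiling(w / window)
  out <- matrix(NA_real_, ho, wo)
  agg <- if (fun == "max") max else mean
  for (i in seq_len(ho)) {
    ri <- ((i - 1) * window + 1):min(i * window, h)
    for (j in seq_len(wo)) {
      cj <- ((j - 1) * window + 1):min(j * window, w)
      v <- map$lat[ri, cj]
      v <- v[!is.na(v)]
      if (length(v) > 0) out[i, j] <- agg(v)
    }
  }
  structure(list(lat = out, valid = !is.na(out),
                 pixel_size_um = map$pixel_size_um * window,
                 frame_rate = map$frame_rate),
            class = "pixel_lat_map")
}

# Quadratic least-squares fit T(x,y) = a + bx + cy + dx^2 + exy + fy^2
# over points centred at the window origin. Returns the 6 coefficients.
quad_fit <- function(x, y, t) {
  X <- cbind(1, x, y, x^2, x * y, y^2)
  qr.coef(qr(X), t)
}

#' Smooth a pooled LAT map by local 2D quadratic fits
#'
#' For every valid pooled pixel, a quadratic surface
#' \code{T(x, y) = a + bx + cy + dx^2 + exy + fy^2} is least-squares
#' fitted to the valid pixels in a square window centred on it; the
#' smoothed value is the fitted constant term \code{a} (the surface
#' evaluated at the window centre). The window is specified in microns
#' and converted to pooled pixels.
#'
#' @param map a pooled \code{\link{pixel_lat_map}}.
#' @param window_um fitting window side length, um (default 600, matching
#'   a typical organoid radius).
#' @return list with \code{map} (smoothed \code{pixel_lat_map}) and
#'   \code{coeffs} (array h x w x 6 of fit coefficients a..f) and
#'   \code{residual_rms} (matrix).
#' @export
smooth_lat <- function(map, window_um = 600) {
  stopifnot(inherits(map, "pixel_lat_map"))
  win_px <- max(3, round(window_um / map$pixel_size_um))
  half <- floor(win_px / 2)
  h <- nrow(map$lat); w <- ncol(map$lat)
  out <- matrix(NA_real_, h, w)
  coeffs <- array(NA_real_, c(h, w, 6))
  rms <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!map$valid[i, j]) next
      ri <- max(1, i - half):min(h, i + half)
      cj <- max(1, j - half):min(w, j + half)
      sub <- map$lat[ri, cj]
      ok <- which(!is.na(sub), arr.ind = TRUE)
      if (nrow(ok) < 6) next
      xs <- ri[ok[, 1]] - i     # local coordinates, pooled-pixel units
      ys <- cj[ok[, 2]] - j
      ts <- sub[ok]
      cf <- quad_fit(xs, ys, ts)
      if (any(is.na(cf))) next  # rank-deficient neighbourhood
      out[i, j] <- cf[1]
      coeffs[i, j, ] <- cf
      fit <- cbind(1, xs, ys, xs^2, xs * ys, ys^2) %*% cf
      rms[i, j] <- sqrt(mean((ts - fit)^2))
    }
  }
  sm <- structure(list(lat = out, valid = !is.na(out),
                       pixel_size_um = map$pixel_size_um,
                       frame_rate = map$frame_rate),
                  class = "pixel_lat_map")
  list(map = sm, coeffs = coeffs, residual_rms = rms)
}

#' Planar conduction-velocity field from a 2D LAT map
#'
#' Central-difference gradients
#' \code{grad_x = (T(x+1, y) - T(x-1, y)) / (2 Dpixel)} (and likewise in
#' y), direction = normalised gradient, speed = inverse gradient
#' magnitude converted to cm/s. Pixels with any invalid neighbour or a
#' gradient below tolerance are masked.
#'
#' @param map a (smoothed) \code{\link{pixel_lat_map}}.
#' @param pixel_size_um distance per pixel, um; defaults to the map's.
#' @param grad_tol gradient-magnitude tolerance, s/cm.
#' @return object of class \code{cv_field2d}: list with \code{speed}
#'   (cm/s), \code{dir_x}, \code{dir_y}, \code{valid},
#'   \code{pixel_size_um}.
#' @export
cv_2d <- function(map, pixel_size_um = NULL, grad_tol = 1e-6) {
  stopifnot(inherits(map, "pixel_lat_map"))
  if (is.null(pixel_size_um)) pixel_size_um <- map$pixel_size_um
  t <- map$lat
  h <- nrow(t); w <- ncol(t)
  if (h < 3 || w < 3) stop("cv_2d: map must be at least 3 x 3")
  px_cm <- pixel_size_um * 1e-4
  gx <- matrix(NA_real_, h, w); gy <- matrix(NA_real_, h, w)
  gx[2:(h - 1), ] <- (t[3:h, ] - t[1:(h - 2), ]) / (2 * px_cm)
  gy[, 2:(w - 1)] <- (t[, 3:w] - t[, 1:(w - 2)]) / (2 * px_cm)
  gmag <- sqrt(gx^2 + gy^2)
  valid <- is.finite(gmag) & gmag > grad_tol
  structure(list(speed = ifelse(valid, 1 / gmag, NA_real_),
                 dir_x = ifelse(valid, gx / gmag, NA_real_),
                 dir_y = ifelse(valid, gy / gmag, NA_real_),
                 valid = valid, pixel_size_um = pixel_size_um),
            class = "cv_field2d")
}

#' @export
print.cv_field2d <- function(x, ...) {
  sp <- x$speed[x$valid]
  cat(sprintf("2D CV field: %d x %d px, %d valid; mean %.3g, median %.3g cm/s\n",
              nrow(x$speed), ncol(x$speed), sum(x$valid),
              mean(sp), stats::median(sp)))
  invisible(x)
}

#' Full calcium-movie isochrone pipeline
#'
#' Convenience wrapper: mask, per-pixel half-max LATs, 5 x 5 max pooling,
#' local quadratic smoothing, planar CV field.
#'
#' @param stack a \code{frame_stack}.
#' @param threshold_frac mask dynamic-range threshold.
#' @param occlusion optional occlusion geometry for the mask.
#' @param neighborhood local-mean neighbourhood (odd).
#' @param pool_window pooling window.
#' @param window_um smoothing window, um.
#' @return list with \code{mask}, \code{pixel_map}, \code{pooled},
#'   \code{smoothed} (the smoothed map), \code{fit} (coefficients and
#'   residuals), \code{cv}.
#' @export
calcium_pipeline <- function(stack, threshold_frac = 0.5, occlusion = NULL,
                             neighborhood = 3, pool_window = 5,
                             window_um = 600) {
  mask <- build_mask(stack, threshold_frac, occlusion)
  pm <- pixel_lat(stack, mask, neighborhood)
  pooled <- pool_lat(pm, pool_window)
  sm <- smooth_lat(pooled, window_um)
  cv <- cv_2d(sm$map)
  list(mask = mask, pixel_map = pm, pooled = pooled, smoothed = sm$map,
       fit = sm[c("coeffs", "residual_rms")], cv = cv)
}
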