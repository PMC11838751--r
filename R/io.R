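#' Write / read a multichannel recording as delimited text + JSON sidecar
#'
#' Signals are stored one channel per column (tab-separated, header =
#' channel ids, microvolts); the JSON sidecar carries the sampling rate,
#' units, start time and optional provenance fields.
#'
#' @param rec a \code{\link{mea_recording}}.
#' @param path output path for the signal table; the sidecar is written
#'   at \code{paste0(path, ".json")}.
#' @param meta optional named list merged into the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, meta = list()) {
  stopifnot(inherits(rec, "mea_recording"))
  m <- t(rec$signals)
  colnames(m) <- rec$channel_ids
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- c(list(fs = rec$fs, units = "uV", t0 = rec$t0,
                    channel_ids = rec$channel_ids,
                    tool = "shellmea", version = "0.1.0"), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  mea_recording(t(m), fs = sidecar$fs, channel_ids = sidecar$channel_ids,
                t0 = if (is.null(sidecar$t0)) 0 else sidecar$t0)
}

#' Write / read an electrode layout as JSON
#'
#' The JSON carries channel ids, latitudes/longitudes with an explicit
#' unit key (degrees) and the sphere radius in microns.
#'
#' @param layout an \code{\link{shell_layout}}.
#' @param path JSON file path.
#' @return \code{path}, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "electrode_layout"))
  jsonlite::write_json(list(
    angle_unit = "degrees", radius_um = attr(layout, "radius_cm") * 1e4,
    electrodes = data.frame(channel_id = layout$channel_id,
                            lat_deg = layout$lat * 180 / pi,
                            lon_deg = layout$lon * 180 / pi)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$angle_unit, "degrees"))
    stop("read_layout: unsupported angle unit '", j$angle_unit, "'")
  e <- j$electrodes
  out <- data.frame(channel_id = e$channel_id,
                    lat = e$lat_deg * pi / 180, lon = e$lon_deg * pi / 180,
                    stringsAsFactors = FALSE)
  structure(out, radius_cm = j$radius_um / 1e4,
            class = c("electrode_layout", "data.frame"))
}

#' Serialise a LAT table to CSV
#'
#' Long format: channel_id, beat, lat_s, relative_s.
#'
#' @param lat_table a \code{\link{build_lat_table}} result.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_lat_table <- function(lat_table, path) {
  stopifnot(inherits(lat_table, "lat_table"))
  n_b <- ncol(lat_table$lat)
  df <- data.frame(
    channel_id = rep(lat_table$channel_ids, n_b),
    beat = rep(seq_len(n_b), each = nrow(lat_table$lat)),
    lat_s = as.vector(lat_table$lat),
    relative_s = as.vector(lat_table$relative))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a calcium frame stack as multi-page TIFF
#'
#' Frames are normalised to [0, 1] for storage as 32-bit float TIFF; the
#' frame rate and pixel size are restored from arguments on read.
#'
#' @param stack a \code{frame_stack} (array t x h x w).
#' @param path TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  frames <- lapply(seq_len(dim(stack)[1]), function(k) stack[k, , ])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_movie
#' @param frame_rate,pixel_size_um acquisition metadata to attach on read.
#' @export
read_movie <- function(path, frame_rate, pixel_size_um) {
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(frames), nrow(frames[[1]]),
                          ncol(frames[[1]])))
  for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
  structure(arr, frame_rate = frame_rate, pixel_size_um = pixel_size_um,
            class = "frame_stack")
}

#' Pipeline configuration with YAML round trip
#'
#' Collects every tunable parameter of the pipeline with documented
#' defaults; \code{write_config}/\code{read_config} round-trip losslessly
#' through YAML.
#'
#' @param ... overrides of the default fields (see the default list in
#'   the function body / the methods vignette).
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    lowpass_hz = 1000, notch_hz = 60, notch_q = 30, downsample_to = 10000,
    zero_phase = TRUE, filter_order = 4,
    threshold_k = 8, refractory_s = 0.2, window_s = c(0.05, 0.15),
    lat_method = "slope", fpd_blanking_s = 0.05,
    epsilon_cm = NA, grid_n_lat = 64, grid_n_lon = 128,
    calcium_threshold_frac = 0.5, calcium_neighborhood = 3,
    calcium_pool_window = 5, calcium_window_um = 600,
    seed = 1, output_dir = ".")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown) > 0)
    stop("pipeline_config: unknown field(s): ", paste(unknown, collapse = ", "))
  defaults[names(ov)] <- ov
  structure(defaults, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param cfg a \code{pipeline_config}.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the electrophysiology mapping pipeline on one recording
#'
#' Preprocess, detect beats and LATs, compute waveform metrics, build the
#' 3D isochrone map and CV field.
#'
#' @param rec a raw \code{\link{mea_recording}}.
#' @param layout an \code{\link{shell_layout}}.
#' @param cfg a \code{\link{pipeline_config}}.
#' @return list with \code{preprocessed}, \code{lat_table},
#'   \code{metrics}, \code{order}, \code{isochrone}, \code{cv}.
#' @export
run_pipeline <- function(rec, layout, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "mea_recording"),
            inherits(layout, "electrode_layout"))
  fcfg <- filter_config(lowpass_hz = cfg$lowpass_hz, notch_hz = cfg$notch_hz,
                        notch_q = cfg$notch_q,
                        downsample_to = cfg$downsample_to,
                        zero_phase = cfg$zero_phase, order = cfg$filter_order)
  pp <- preprocess(rec, fcfg)
  lt <- build_lat_table(pp, method = cfg$lat_method,
                        threshold_k = cfg$threshold_k,
                        refractory = cfg$refractory_s,
                        window = cfg$window_s)
  metrics <- waveform_metrics(pp, lt, blanking = cfg$fpd_blanking_s)
  ord <- activation_order(lt)
  eps <- if (is.na(cfg$epsilon_cm)) NULL else cfg$epsilon_cm
  iso <- build_isochrone(layout, rowMeans(lt$relative, na.rm = TRUE),
                         grid = sphere_grid(cfg$grid_n_lat, cfg$grid_n_lon,
                                            attr(layout, "radius_cm")),
                         epsilon = eps)
  list(preprocessed = pp, lat_table = lt, metrics = metrics, order = ord,
       isochrone = iso, cv = cv_field(iso))
}
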