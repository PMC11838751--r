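# Shared fixtures: all synthetic, generated in code.

fixture_layout <- function() shell_layout()

# Short noiseless recording for fast unit tests (5 beats, ~8 s @ 30 kHz)
quick_sim <- function(n_beats = 5, sigma_white = 0, seed = 1,
                      origin_jitter = 0, fs = 30000,
                      template = waveform_template()) {
  simulate_recording(fixture_layout(),
                     wavefront_model(n_beats = n_beats),
                     template,
                     noise_model(sigma_white = sigma_white, seed = seed),
                     fs = fs, origin_jitter = origin_jitter)
}

# Build a lat_table object directly (for order/confusion tests that do not
# need signal-level detection)
make_lat_table <- function(lat_matrix) {
  structure(list(
    lat = lat_matrix,
    relative = sweep(lat_matrix, 2, apply(lat_matrix, 2, min)),
    mean_lat = rowMeans(lat_matrix),
    channel_ids = rownames(lat_matrix),
    windows = list(), method = "slope", fs = 10000), class = "lat_table")
}

# Truth LAT matrix (channels x beats) from a simulate_recording truth table
truth_matrix <- function(truth, n_ch = 16) {
  matrix(truth$lat_true, nrow = n_ch, byrow = TRUE)
}
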