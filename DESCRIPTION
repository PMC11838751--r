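Package: shellmea
Title: 3D Spatiotemporal Activation Mapping for Shell Microelectrode Array
    Recordings of Cardiac Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 16-electrode shell microelectrode array
    (MEA) recordings of spontaneously beating cardiac organoids. Detects
    beats with the nonlinear energy operator, extracts local activation
    times (LAT) by maximum negative slope or maximum amplitude, computes
    field-potential waveform metrics (amplitude, beat rate, field potential
    duration) and drug-response summaries, interpolates LATs onto a
    spherical surface with haversine-distance inverse-quadratic radial
    basis functions to build 3D isochrone maps, derives conduction-velocity
    vector fields by finite differences, processes calcium-imaging movies
    into 2D isochrone and conduction-velocity maps, and compares
    hemisphere projections of the 3D maps against the calcium-derived
    maps. Includes a synthetic-data generator producing ground-truth
    wavefronts, multichannel field potentials and matched fluorescence
    movies so the whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
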