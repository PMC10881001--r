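Package: sonovis
Title: Audiovisualization of Spatiotemporal Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to turn dynamic fluorescence imaging movies (widefield or
    volumetric calcium imaging) into synchronized audio-visual artifacts.
    Movies are reduced to nonnegative spatial and temporal components via
    correlation-distance k-means clustering, ROI timecourse extraction and
    per-voxel non-negative least squares fitting. Temporal components are
    sonified either by amplitude-modulating pitched sinusoids ("analog") or
    by detecting supra-threshold transients and encoding them as MIDI note
    events rendered with a built-in additive synthesizer ("digital").
    Spatial components are recombined into color-remixed videos, and audio
    and video streams are muxed into a single playable movie. A synthetic
    movie generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    withr,
    tiff,
    yaml,
    stats,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
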