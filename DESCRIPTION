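Package: fintrack3d
Title: Camera-Based 3D Fish-Object Distance Estimation Pipelines
Version: 0.1.0
Authors@R:
    person("Fintrack", "Developers", email = "fintrack3d@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating three-dimensional fish-to-camera distances
    from stereo and monocular video-derived observation streams, as used to
    quantify avoidance behaviour of farmed fish around intrusive objects in
    aquaculture net pens. Implements four pipelines over pluggable perception
    backends: stereo association of segmentation masks, stereo association of
    detector bounding boxes, sparse feature-match triangulation, and monocular
    metric depth-map lookup. Includes a ByteTrack-style two-stage IOU
    multi-object tracker, a Hungarian assignment solver, a synthetic stereo
    fish-scene simulator with ground truth, and evaluation statistics
    (per-frame closest-fish distance, per-case summaries, mean absolute error
    with Student-t confidence intervals against an independent reference, and
    Savitzky-Golay trajectory smoothing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
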