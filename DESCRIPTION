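Package: hearttrace
Title: Heartbeat Quantification from Time-Lapse Video of a Tubular Heart
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the intermittent, peristaltic heartbeat of
    tubular invertebrate hearts from grayscale video. Extracts per-ROI
    contraction traces by thresholded pixel counting, detects contraction
    troughs, bursts and prolonged pauses, overlays beats into a four-phase
    cycle profile, estimates the peristaltic wave speed from the
    cross-correlation lag between two regions, and computes cardiac indices
    (end-diastolic and end-systolic volume, stroke volume, ejection fraction,
    cardiac output, relative flow rate and circulation time) from a
    cylindrical heart model. Includes a synthetic peristaltic-heart video
    generator with machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tiff,
    png,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
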