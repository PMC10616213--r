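Package: dynaoi
Title: Dynamic Area-of-Interest Analysis for Wide-Screen Head-Mounted Eye Tracking
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing gaze on moving areas of interest (AOIs) recorded
    with a head-mounted eye tracker on a wide (100 degree) three-screen display.
    Pools per-surface gaze exports from fiducial-marker surface tracking into one
    screen-centered coordinate stream, cleans the gaze signal (median spike
    filtering, confidence and on-screen gating, short-gap interpolation, blink-gap
    padding, uniform 240 Hz monotone-Hermite resampling), annotates moving AOIs on
    video by semi-automatic tracking or keyframe interpolation, matches gaze to
    AOIs frame-by-frame with eccentricity-aware visual-angle margins, and computes
    dwell-time and time-to-first-entry metrics, with gaze/AOI overlay rendering and
    a fully scripted synthetic-scenario generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
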