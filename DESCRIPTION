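Package: musecho
Title: Quantification of Murine High-Frequency Ultrasound Imaging
Version: 0.1.0
Authors@R:
    person("musecho", "developers", email = "musecho@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of small-animal high-frequency ultrasound
    examinations: vessel diameter waveforms from B-mode cine loops by edge
    detection and contour tracking, Doppler spectrogram envelope extraction
    with velocity summary indices (PSV, EDV, MV, RI, PI, E/A), local pulse
    wave velocity from the diameter-velocity loop, pulse pressure via the
    inverted Bramwell-Hill relation, wall shear rate, left-ventricular
    function metrics from traced contours, speckle-tracking strain and
    strain rate, a hepatorenal gray-level steatosis index, and cohort-level
    nonparametric group comparison. Includes a synthetic phantom generator
    producing speckle-textured cine loops, spectrograms and parenchyma
    textures with known ground truth, so the whole pipeline is testable
    without acquired image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
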