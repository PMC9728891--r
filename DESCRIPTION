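Package: neurodyn
Title: Spatiotemporal Dynamics of Self-Paced Decision fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for self-paced event-related fMRI experiments in
    which trial duration equals the subject's decision time. Provides a
    synthetic multi-subject BOLD generator with planted stage structure and
    correlated noise, light signal preparation (slow-drift removal, Gaussian
    volume smoothing, atlas ROI extraction, fALFF component filtering, subject
    inclusion rules), event-related GLM contrasts with a canonical double-gamma
    HRF, trial-anchored dynamic functional-connectivity consensus graphs,
    trial-length-normalized FIR response estimation with sliding-window
    top-peak consensus maps and condition differences, and decoding of the
    trial response from pairwise-correlation features under cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    glmnet,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
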