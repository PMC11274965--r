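Package: intentmvpa
Title: Multivariate Decoding of Motor Intention from Event-Related fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for region-of-interest multivariate pattern analysis of
    event-related fMRI designs in which cued motor intention precedes
    kinesthetic motor imagery. Implements the full analysis chain: balanced
    event schedules on a repetition-time grid with a hemodynamic delay shift,
    z-normalization, Gaussian FWHM smoothing and ROI masking, linear
    support-vector-machine decoding with stratified cross-validation, and
    effect mapping, a normalized-mutual-information weighting of SVM weights
    that localizes the voxels driving the classifier. Includes physiological
    control decoders (EMG waveform-length features with a Karhunen-Loeve
    transform and a feed-forward neural network; per-TR linear discriminant
    analysis of gaze position) and a synthetic-data generator emulating the
    statistical structure of such experiments, so every stage is testable
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    MASS,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
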