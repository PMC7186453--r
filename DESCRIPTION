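Package: tdcsmap
Title: Concurrent Mapping of tDCS Current-Induced Magnetic Fields and
    BOLD Responses from Dual-Echo EPI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring the magnetic field induced by transcranial
    direct current stimulation (tDCS) concurrently with BOLD fMRI using a
    dual-echo echo-planar imaging (DE-EPI) acquisition. The phase of the MRI
    signal encodes the current-induced field along the scanner axis (Bz),
    while the second-echo magnitude carries BOLD contrast. The package
    simulates current-induced Bz maps from explicit current paths via the
    Biot-Savart law, generates synthetic dual-echo phantom and cohort
    acquisitions with the field encoded in the phase, recovers unwrapped
    phase with a quality-guided 4D region-growth algorithm, estimates
    field-per-milliampere maps with a general linear model, bounds
    intravoxel-dephasing confounds on the BOLD signal with two closed-form
    models, and provides the validation statistics used to assess such
    measurements (spatial correlation, range-restricted regression, paired
    tests, ICC, DICE, and dual-regression-style component testing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
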