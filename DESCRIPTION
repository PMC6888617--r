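Package: rher
Title: Human-Animal Discrimination for IR-UWB Radar Vital-Sign Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for distinguishing human from animal subjects in
    non-contact vital-sign monitoring with impulse-radio ultrawideband
    (IR-UWB) radar. Implements the full processing chain: slow-time
    clutter/DC removal and low-pass FIR filtering, energy-based target
    localization with a segment-calibrated human energy gate, variational
    mode decomposition (VMD) of the target's slow-time signal via the
    ADMM spectral updates, and the respiratory-and-heartbeat energy ratio
    (RHER) classifier. Includes a physics-based echo simulator (chest
    kinematics modulating a Gaussian-envelope ultrawideband pulse plus
    static multipath and noise) and species physiological presets, so the
    whole pipeline can be exercised without radar hardware.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
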