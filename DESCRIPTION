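Package: emginfo
Title: Information-Theoretic Evaluation of EMG Amplitude Estimators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates surface electromyogram (EMG) processing techniques by the
    amount of Shannon information they extract about the motor stimulus (arm
    angular position). Implements four windowed time-domain amplitude
    estimators (root mean square, absolute mean value, difference absolute
    mean value, and variance), plug-in mutual information from discretized
    stimulus-response co-occurrence matrices for both static (labelled
    position) and dynamic (continuous angle ramp) contraction protocols,
    window-length (segmentation) optimization with per-subject normalization,
    and analyses of movement-direction hysteresis and inter-electrode
    distance. Includes a seeded synthetic-EMG generator (amplitude-modulated
    band-limited Gaussian noise) emulating the static and dynamic abduction /
    adduction protocols, so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
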