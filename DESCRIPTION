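Package: gaitmuscle
Title: Inverse-Dynamics Based Estimation of Muscle Forces During Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the muscle force-sharing (redundancy) problem of gait from
    inverse-dynamics joint moments. Implements per-frame static optimization
    under four recruitment criteria (squared forces, squared relative forces,
    squared stresses, min/max relative force), three physiological variants of
    Hill-type musculotendon dynamics (elastic tendon with activation dynamics,
    rigid tendon with and without activation time response), and an all-frame
    synergy optimization with B-spline synergy activations. Includes EMG
    envelope extraction and cross-correlation validation, paired statistical
    comparison of methods, subject-specific musculotendon length scaling, and a
    synthetic gait-cycle generator so the full pipeline can be exercised and
    tested without subject data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    splines,
    boot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
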