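Package: nfkbsync
Title: Damped NF-kB Oscillator Dynamics, Entrainment and Transcription Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic ODE model of NF-kB nuclear-cytoplasmic dynamics with
    two negative feedbacks (IkBa and A20), driven by constant, square-wave or
    sawtooth TNF-alpha forcing. Provides fixed-point and Jacobian eigenvalue
    classification of damped versus sustained oscillatory regimes, randomized
    parameter stability scans, single-cell trace analysis (significant-peak
    detection, phase assignment, inter-peak periods, entropy-based synchrony
    intensity), parameter fitting of nuclear-to-cytoplasmic intensity and
    gene-expression fold-change time courses (Metropolis exploration plus
    Levenberg-Marquardt refinement), soft clustering of expression profiles
    with membership cores and enrichment tests, and seed-reproducible
    synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
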