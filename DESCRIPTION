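Package: affectdyn
Title: Cross-Species Analysis of Biphasic Affective Neural and Behavioral Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing stimulus-aligned electrophysiology and
    eye-closure behaviour in repeated air-puff paradigms, where an early
    reflexive blink is followed by a slower affective eye closure. Implements
    multitaper peri-event spectrograms with double z-scoring, sign-split
    non-negative matrix factorization of spectrotemporal responses,
    paired cluster-based permutation tests, population coding dimensions
    with nuisance orthogonalization, single-unit response clustering and
    regional rise/decay timing, a two-phase first-order model of affective
    state (fast saturating broadcast followed by slow persistence),
    intrinsic-timescale estimation, phase-locking-value coupling, and
    detection of band-limited oscillations over a 1/f background. A seeded
    synthetic-session generator with stored ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    minpack.lm,
    pracma,
    cluster,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'affectdyn-package.R'
    'AllClasses.R'
    'behavior.R'
    'dimensions.R'
    'dynamics.R'
    'factors.R'
    'netstate.R'
    'oscillations.R'
    'permcluster.R'
    'pipeline.R'
    'spectral.R'
    'spiking.R'
    'synth.R'
    'utils.R'
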