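Package: pausekit
Title: Steady-State Kinetics of Transcription Initiation and Promoter-Proximal Pausing from Nascent RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based inference of transcription initiation and
    promoter-proximal pause-escape rates from nascent RNA sequencing
    (PRO-seq/GRO-seq) read counts at steady state. Implements a
    continuous-time Markov model of single-polymerase movement with
    closed-form maximum-likelihood estimators, an expectation-maximization
    algorithm for cell-to-cell variability in pause-site position
    (truncated-Gaussian mixture), and a steric-hindrance extension that
    recovers landing-pad occupancy and potential initiation rates from
    effective ones. Includes a stochastic simulator of RNA polymerase
    traffic with collision exclusion across many cells, a Poisson
    read-count sampler, strand-specific coverage-track ingestion
    (bigWig/bedGraph), and calibration and half-life workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
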