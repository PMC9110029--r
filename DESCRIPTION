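Package: secsteps
Title: Kinetic Analysis of Stepwise Protein Transport Through the Sec Translocon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-resolution luminescence assays of
    SecA/SecYEG-mediated protein translocation. Implements the sequential
    kinetic transport model (binding equilibrium, initiation, n transport
    steps, failure/restart and irreversible blocking) as an ODE system, the
    lag + single-exponential trace model, model selection over the number of
    transport steps by normalised RMSD scanning (single-segment and
    two-segment variants), the proton-motive-force effect statistic with
    SEM-derived bounds, proteome-scale Lys/(Lys+Arg) secretion-bias analysis
    with Sturges-rule histograms and Gaussian fits, and sliding-window
    protein property profiles. Includes synthetic-data generators that
    emulate the transport assay and annotated proteomes for fully
    reproducible pipeline tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Biostrings,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
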