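Package: hybrikin
Title: Nucleation-Zippering Kinetics and Thermodynamics of Oligonucleotide Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the annealing kinetics of short DNA and RNA oligonucleotides with
    mismatches and bulges. Implements nearest-neighbor duplex thermodynamics with
    defect penalties, the analytical nucleation-zippering association-rate model with
    per-defect-class zippering efficiencies, a kinetic Monte Carlo simulator of
    double-ended duplex zippering with an exact absorbing-chain solver, mass-action
    competition dynamics that capture transient low-accuracy hybridization states,
    stopped-flow and melting-curve fitting, off-target site combinatorics in random
    sequence, and seeded synthetic-data generators for all of the above.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
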