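Package: decaykit
Title: RNA Decay Kinetics from Dual-Fraction 4sU Pulse Labelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: First-order RNA kinetic rate inference (synthesis, processing,
    degradation) from short 4-thiouridine metabolic-labelling pulses in which
    newly synthesized and pre-existing RNA fractions are sequenced separately
    and quantified at intronic and exonic features. Provides closed-form
    solutions of the two-compartment premature/mature model, cross-library
    normalization by steady-state conservation, per-gene nonlinear
    least-squares rate fitting with condition comparison under FDR control,
    transcript classification by subcellular localization, translation
    efficiency and conserved-ORF micropeptide flagging, miRISC-binding
    evidence from AGO2 peak density and miRNA seed-match scanning, and a
    synthetic-data generator that emulates a DICER loss-of-function study
    design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
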