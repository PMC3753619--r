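Package: duplexmelt
Title: Thermodynamics of Duplex DNA Melting Adjacent to G-Quadruplex and
    i-Motif Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for UV and CD thermal melting analysis of short DNA
    duplexes, designed for experiments that probe how neighbouring
    G-quadruplex or i-motif structures destabilize double-helical DNA.
    Implements the two-state equilibrium forward model for unimolecular and
    bimolecular transitions, the inverse pipeline from raw melting traces
    (baseline correction, folded fraction, melting temperature, van't Hoff
    regression), replicate aggregation with 1-sigma errors, delta-delta-G
    destabilization statistics with quadrature error propagation, one-way
    ANOVA with Bonferroni correction, putative quadruplex/i-motif sequence
    scanning, and a synthetic melting-curve generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
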