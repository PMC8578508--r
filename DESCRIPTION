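Package: hdxdimer
Title: Differential HDX-MS and Biophysical Analysis of Phosphorylation-Dependent Protein Dimerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for studying phosphorylation-driven
    conformational change and dimerization of multidomain proteins such as the
    BET-family reader BRD4. Implements residue-level differential hydrogen-deuterium
    exchange mass spectrometry (HDX-MS) with a combined absolute/relative
    significance rule and per-residue projection over overlapping peptides,
    EX1/EX2 kinetic classification from isotopic envelopes by binomial-mixture
    deconvolution, cross-linking MS contact-map logic for monomer/dimer fractions,
    construct-level utilities (intact average/monoisotopic masses, CK2
    consensus-motif scanning, coiled-coil heptad annotation), NanoBRET
    quantification with one-site-total and four-parameter logistic fits, and
    hydrodynamic conversions (s20,w correction, Svedberg/frictional-ratio
    relations). A built-in Linderstrom-Lang exchange simulator generates peptide
    maps, uptake tables and isotopic envelopes so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
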