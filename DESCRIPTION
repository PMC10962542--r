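Package: pepbiophys
Title: Biophysical Characterization Pipeline for Constrained Helical Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis workflow for constrained (stapled) peptide
    inhibitors of protein-protein interactions. Covers variant design by
    i,i+4 cysteine-pair scanning with hot-spot exclusion; fluorescence
    anisotropy processing with Morrison tight-binding direct titrations and
    four-parameter logistic competition (IC50) fits, including the
    -RT ln(fold-change) free-energy comparison; circular dichroism mean
    residue ellipticity and percent-helicity estimation from the 222 nm
    signal; random-coil-referenced NMR secondary chemical shifts with
    helical-segment calling; and simulators with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
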