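Package: aluspectra
Title: Branching-Process Allele Frequency Spectra for Alu Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Neutral-evolution analysis of transposable-element copy-number
    spectra with the Griffiths-Pakes discrete-time branching process with
    infinite-allele mutations. Implements exact probability generating
    function algebra for the linear-fractional (geometric-tail) offspring
    law via Moebius maps, computes the limit allele frequency spectrum,
    fits the offspring parameters (b, p) to allele-class count tables by
    maximum likelihood, tests goodness of fit with a parametric-bootstrap
    chi-square procedure, and cross-validates everything with a forward
    simulator of the same process. Ships the AluY subfamily class-count
    tables used throughout as a plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
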