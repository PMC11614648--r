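Package: splitintein
Title: Design and Evaluate Split-Intein Trans-Splicing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for designing protein trans-splicing experiments with
    naturally split inteins of the DnaE family. Candidate split sites in a
    target protein are enumerated, scored against a position-specific
    extein-impact matrix covering the six residues flanking the splice
    junction (N-3..C+3), constrained on the catalytic C+1 residue, annotated
    with secondary structure, and ranked. Chosen sites are turned into
    deliverable constructs: N- and C-precursor open reading frames carrying
    intein halves and affinity tags, codon back-translated DNA with
    GC-minimizing or max-frequency codon choice, restriction-site cloning
    flanks, and overlap-extension PCR fragment tilings with primer melting
    temperatures. Companion assay models quantify validation experiments:
    four-parameter logistic transduction dose-response fitting with inverse
    dose prediction, qPCR standard curves with amplification-efficiency
    acceptance rules and absolute titer quantification, and densitometry
    normalization. Seeded generators for synthetic proteins, impact matrices,
    dose-response and dilution-series data make the whole pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
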