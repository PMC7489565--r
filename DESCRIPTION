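Package: pksmith
Title: Motif-Based PKS Domain Annotation and Tetronate Pathway Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers the product of a type I modular polyketide synthase gene
    cluster from sequence: reference-anchored motif annotation of KS, AT, DH,
    ER and KR domains (including substrate-selectivity and stereochemistry
    calls), collinear assembly of the implied linear polyketide chain,
    position-by-position comparison against a retrobiosynthetic target
    decomposition, tailoring-pathway reaction bookkeeping with gene-knockout
    product simulation, positive-mode adduct m/z computation with Delta-mass
    metabolite diagnosis, and in-frame deletion design arithmetic. Ships a
    seeded synthetic-fixture generator and a packaged description of the
    tetromadurin (mad) cluster of Actinomadura verrucosospora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
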