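Package: cytb561anno
Title: Annotation and Comparative Analysis of Cytochrome b561 Family Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for annotating cytochrome b561 (cytb561) transmembrane
    oxidoreductases. Anchors family members on the four conserved
    heme-coordinating histidines (H1-H4), expresses residues in
    histidine-relative coordinates, classifies sequences by percent identity
    against human reference cytb561s, scores alignment-column conservation,
    scans diagnostic sequence motifs (KXXXXKXH, dileucine sorting signals,
    the DOMON SXDXXMGXD aspartate pocket), evaluates a ferric-reductase
    residue checklist derived from duodenal cytochrome b561, and provides
    structure utilities (pruned superposition, van der Waals contacts,
    geometric hydrogen bonds). A seeded synthetic-family generator with full
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
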