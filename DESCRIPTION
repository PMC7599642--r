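Package: ribovar
Title: Intragenomic Ribosomal DNA Variation in Cultivated Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of intragenomic 18S ribosomal DNA polymorphism in
    cloned gene copies from cultivated plant cell lines. Calls per-clone
    substitutions against a reference gene and classifies them
    (transition/transversion, cytosine-methylation-associated,
    amination-associated), summarises per-line substitution spectra,
    scans nucleotide diversity in sliding windows and localises hotspot
    regions, collapses clones into ribotypes and builds minimum spanning
    trees and median-joining networks, predicts secondary structures of
    short rRNA segments with a loop-feature census, and summarises
    chromosome and nucleoli counts. A synthetic clone-set generator with
    planted mutation parameters makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
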