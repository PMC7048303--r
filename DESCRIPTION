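Package: dupfate
Title: Paralog Divergence, Whole-Genome Duplication Dating and
    Sex-Chromosome Region Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codon-level divergence estimation between paralogous coding
    sequences (Nei-Gojobori site and pathway counting with Jukes-Cantor
    correction, dN/dS, fourfold-degenerate transversion rates), detection and
    dating of whole-genome duplication events from dS distributions,
    sliding-window and outgroup-anchored branch selection screens, paralog
    expression-divergence classification across a seasonal flower-development
    series, and classification of Y-chromosome regions (male-specific,
    pseudoautosomal-like, repetitive) from pooled male and female read depth,
    together with calibrated simulators that generate every input class with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
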