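Package: dictycomp
Title: Comparative Genomics of Paired Dictyostelid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of the bespoke comparative-genomics
    computations used to contrast a pair of AT-rich social-amoeba genomes:
    simple-sequence-repeat detection with unit-length-specific minimum copy
    numbers, amino-acid homopolymer statistics with composition-based chance
    thresholds, synteny-block construction by single-linkage clustering under
    a gene-window parameter with permutation nulls, an upstream-element
    (DUSE) anchored non-coding RNA screen with stem/bulge structural filters,
    and per-ortholog-pair molecular evolution (Nei-Gojobori dN, conservation
    score) against social-stage expression indices. Includes a synthetic
    paired-genome generator with planted, recorded ground truth so that every
    stage is testable end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
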