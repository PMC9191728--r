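Package: sinescout
Title: Discovery and Characterization of tRNA-Head SINE Retrotransposons
Version: 0.9.0
Authors@R:
    person("Repo", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A tested pipeline for de novo discovery of tRNA-derived short
    interspersed nuclear elements (SINEs) in genome assemblies, and for the
    analysis of SINE-related PIWI-interacting RNAs (piRNAs). Anchors candidate
    loci on RNA polymerase III type-2 promoters (A box / B box) or on external
    tRNA predictions, clusters 1-kb anchored windows by local-alignment
    similarity, calls element boundaries from column conservation, and builds
    family consensus sequences. Families are characterized genome-wide:
    full-length copies at 80 and 90 percent identity, copy-number age
    profiles, target-site duplications, poly(A) and microsatellite tails, and
    dimeric composites. A small-RNA arm filters 26-31 nt reads, masks
    tRNA-derived heads, maps reads with zero mismatches, and produces per-gene
    strand-split intron counts. A seeded synthetic-genome generator with a
    full ground-truth manifest makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    jsonlite,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
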