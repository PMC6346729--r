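Package: introgscan
Title: Windowed Local-Ancestry Scans for Adaptive Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects candidate regions of adaptive introgression in an
    admixed population from chromosome-painting output and phased
    genotypes. Aggregates per-SNP donor ancestry proportions into
    non-overlapping 50-kb windows, computes per-site Hudson FST and
    window averages, calls candidate windows by Chinese-ancestry and
    FST-quantile filters, extends top-ancestry regions, tests QTL
    enrichment in candidate regions with a circular-rotation
    permutation test, and orders regional haplotypes by distance to a
    reference-population consensus. Includes a seeded synthetic-data
    generator (Balding-Nichols donor panels, Markov ancestry tracts,
    QTL tables) so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
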