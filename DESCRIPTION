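Package: nucorg
Title: Genome-Wide Enrichment, Nucleosome Occupancy and Nuclear Zone
    Analysis for Chromatin Organization Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for three complementary assays of chromatin
    organization in fission yeast: genome-wide feature-class enrichment of
    ChIP-chip and DamID log2 signal tracks with a circular-permutation null
    that respects the spatial autocorrelation of tiling-array probes;
    per-feature nucleosome-occupancy comparison between paired genotypes
    with an exact, tie-aware signed-rank test; and the three-equal-volume-
    zone nuclear localization assay with chi-square strain comparisons.
    A synthetic-data generator emulates the statistical structure of the
    inputs (autocorrelated probe signals with class effects, classified
    genome annotations, paired negative-binomial occupancy counts, nuclear
    spot positions with tunable peripheral bias) so that every stage is
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
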