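Package: shmirtools
Title: Design of shRNAmir Guides and Quantification of Reporter
    Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing microRNA-embedded short hairpin RNAs
    (shRNAmir) against a target mRNA and for quantifying the resulting
    knockdown in histological image data. The design side enumerates
    21-nt siRNA candidates on a reference isoform, ranks them with a
    pluggable scorer, filters for coverage of all transcript isoforms
    and for off-target complementarity (no contiguous match longer than
    15 nt to any other transcript, screened with a 16-mer index),
    transforms survivors into fully overlapping 22-nt mirE duplexes with
    the miR-30a first-position sense mismatch, and embeds them into mirE
    or polycistronic mir17-19b scaffold templates before assembling
    annotated expression constructs with restriction-site validation.
    The quantification side builds ordinal marker-by-reporter
    contingency tables, runs chi-square goodness-of-fit against
    untreated category ratios, the asymptotic linear-by-linear
    association trend test, Pearson trends on ordered proportions,
    rank-sum density comparisons and penetrance; measures per-cell
    intensities from label masks after background normalization; and
    evaluates segmentations by intersection-over-union. A synthetic-data
    module generates transcriptome fixtures with planted off-target
    runs, striatal co-expression cell tables with configurable knockdown
    and channel leakage, and rendered two-channel images with truth
    masks, so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
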