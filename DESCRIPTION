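Package: promscreen
Title: Mining Strong Constitutive Promoters from Bacterial RNA-Seq Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens a bacterial genome for strong constitutive promoters from
    per-gene RNA-seq read counts: genes are ranked by raw read counts within
    each sample, the top fraction of every sample is intersected across
    conditions, and the strand-aware upstream intergenic region of each
    surviving gene is extracted from the annotation (circular replicons
    supported) and filtered by a minimum length. Also provides the quantitation
    arithmetic used to characterise such promoters downstream: relative
    reporter (luciferase) strength against a reference promoter, acetylene
    reduction nitrogenase activity, linear standard-curve fitting and
    inversion for colorimetric ammonium assays, 2^-ddCt relative expression,
    fold-change ratios, and one-way ANOVA with Tukey pairwise comparisons.
    A synthetic-data generator produces annotated circular genomes and count
    matrices with planted constitutive and condition-specific genes so the
    whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
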