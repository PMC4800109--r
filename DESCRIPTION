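Package: crcprofiler
Title: Instability, Methylation and Expression Profiling of Wnt-Inactive Colorectal Cancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular profiling of colorectal cancers that lack
    beta-catenin/TCF regulated transcription. Parses ISCN-style metaphase
    karyotypes and computes chromosomal-instability indices (aneuploid index,
    centromere-number variability, recurrence-filtered rearranged-chromosome
    counts) together with CGH copy-number-change counting and classification
    against published MSI/MSS reference ranges; computes MS-MLPA methylation
    dosage ratios with normal-tissue-derived hypermethylation thresholds and
    per-tumor hypermethylation burden; classifies microsatellite instability by
    the Bethesda-panel rule and calls loss of heterozygosity from allele
    ratios; performs fold-change/Benjamini-Hochberg differential expression and
    size-weighted centroid-linkage hierarchical clustering; and ships seeded
    synthetic-cohort generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
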