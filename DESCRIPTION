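Package: episig
Title: Epigenome Signature Discovery for High-Risk Acute Promyelocytic Leukemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for chromatin-state and methylation signature
    discovery in acute promyelocytic leukemia (APL). Defines promoter and
    enhancer regions from histone-mark peak sets (H3K4me3, H3K4me1), classifies
    activity with H3K27ac and H3K27me3, computes differential enrichment
    statistics (exact Wilcoxon signed-rank and rank-sum tests, fold-change
    outlier calling, a size-factor-normalized negative-binomial test with
    Benjamini-Hochberg FDR), derives supervised whole-genome bisulfite
    sequencing CpG methylation signatures that separate high-risk from
    standard-risk cases, and applies a multi-stage variant filter cascade.
    Ships a deterministic synthetic-data generator with planted ground truth
    so every stage is testable end to end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
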