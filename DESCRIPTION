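Package: epiTC
Title: Classification of Tissue-Specific and Tissue-Enhanced Transcript
    Expression in Two-Tissue Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Threshold-based classification of transcripts into
    tissue-specific and tissue-enhanced up- or down-regulated categories
    from RPKM expression profiles measured in two tissues across a short
    induction time course, as used to screen for transcriptional
    regulators of epidermal transfer cell development in cultured Vicia
    faba cotyledons. Provides RPKM computation from read counts with
    flooring and expression gating, fold-change tables against the
    baseline timepoint, the two-stage specific/enhanced classifier,
    delta-delta Ct quantification of validation RT-qPCR data, a
    negative-binomial synthetic count-matrix generator with planted
    category truth for benchmarking, and TSV/JSON input-output around a
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Classification, qPCR
RoxygenNote: 7.3.3
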