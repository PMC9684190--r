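Package: salternSeasons
Title: Seasonal Expression Analysis of a Saltern Metatranscriptome
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of per-gene mapped-read counts from
    metatranscriptomes recruited to a single reference genome, as used to
    study seasonal gene expression of Haloquadratum walsbyi in solar
    saltern crystallizer ponds. Implements TPM normalization, the
    average-anchored threshold chain for similar/higher expression calls
    and significant seasonal differential expression, high-expression and
    top-N gene tables, genomic-island expression summaries, a sliding
    window scan for differential-expression hotspots along the gene order,
    detection of candidate ecoparalogs (paralogous genes with divergent
    expression within one sample), and a synthetic-data generator with
    planted ground truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Transcriptomics, GeneExpression, Normalization, Metagenomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
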