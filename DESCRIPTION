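Package: doseTx
Title: Dose-Series Transcriptomics of Tryptophan-Supplemented Piglet Liver
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis pipeline for dose-series liver RNA-seq from
    low-birth-weight piglets supplemented with dietary tryptophan (groups L0,
    L4, L8 and a normal-birth-weight control N0, six replicates each). The
    package provides TPM normalisation and per-group base means, low-expression
    filtering and two-group differential expression with an FDR threshold,
    dose-response expression-profile clustering (Minkowski distance, complete
    linkage) with classification into increased-dose-effect, sensitive-dose and
    counter-effect categories, thresholded Pearson co-expression networks with
    hub detection and gene-trait correlation against plasma triglycerides,
    percent-spliced-in (PSI) differential alternative-splicing calls with
    RNA-binding-protein motif enrichment in splice-site binding regions, and
    cross-species ortholog conservation scoring with a species tree. A
    synthetic-data module generates every pipeline input with planted ground
    truth so all stages are testable without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, RNASeq, AlternativeSplicing, GeneExpression,
    Normalization, Clustering, Network
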