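Package: glnregulon
Title: Defining a GlnR Nitrogen Regulon from ChIP-chip and Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the regulon of the actinomycete global
    nitrogen regulator GlnR from two-colour tiling-array ChIP-chip and
    replicated expression time courses. Implements threshold-based peak
    calling on probe ratio tracks with replicate reproducibility and
    empty-vector control subtraction, assignment of binding regions to
    downstream target genes, a dual fold-change filter for nitrogen-responsive
    genes with wild-type versus regulator-mutant dependence calls, bipartite
    GlnR-box consensus scanning and position weight matrix construction, and
    integration of binding, response and dependence evidence into regulon
    categories. A seeded simulator generates tiling tracks with planted
    binding sites and expression matrices with planted regulator-dependent
    genes so that every stage of the pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
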