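Package: etiofoot
Title: DNase-Seq Footprinting and Cis-Regulatory Dynamics for De-Etiolation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing chromatin accessibility and transcription factor
    footprints across a dark-to-light (de-etiolation) time course, with a focus on
    comparing a C4 species against its C3 relative. Implements digital genomic
    footprint detection inside DNase I hypersensitive sites using a strand-aware
    binomial shoulder statistic, hexamer cutting-bias estimation from deproteinated
    DNA and a mixture-model footprint likelihood ratio (FLR) filter, position weight
    matrix scanning with exact p-values, motif-group enrichment against open-chromatin
    backgrounds, binding-trajectory and dark-versus-light correlation analysis,
    expression normalisation with a two-method differential-expression intersection
    contract, cross-species ortholog induction comparison, and a seeded synthetic-data
    generator that emulates the statistical structure of such a study for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
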