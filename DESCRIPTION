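Package: emsight
Title: EMS-Induced Mutation Discovery from Pooled Whole-Genome Resequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies ethyl methanesulfonate (EMS) induced point mutations in
    mutagenized plant families from pooled whole-genome resequencing variant
    calls. Implements depth-based reliable-region masking, sliding-window
    hyperpolymorphic-region removal, cross-family classification of variants
    into shared polymorphisms, family-specific homozygous (spontaneous) and
    family-specific heterozygous (EMS) sets, substitution-spectrum and
    transition/transversion summaries, mutation-density estimation, flanking
    sequence context profiling, a lightweight gene-model based consequence
    annotator with impact tiers, chi-square tests for Mendelian segregation,
    and a ground-truthed simulator of two-family pooled callsets for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
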