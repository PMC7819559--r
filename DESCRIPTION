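Package: urbanmeth
Title: Differential DNA Methylation Analysis for Urban-Forest Habitat Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for reduced representation bisulphite
    sequencing (RRBS) comparisons of two habitats (urban versus forest), as
    applied to wild passerine tissues. Reads Bismark-style per-cytosine
    coverage files, merges CpG strands, applies coverage filters and unites
    samples into a site-by-sample count matrix; detects CpG islands from
    genome sequence with a sliding-window GC/observed-expected rule and
    derives shores, promoters, TSS regions and gene bodies; calls
    differentially methylated sites with a likelihood-ratio test and
    SLIM-adjusted q-values, with a label-permutation null; clusters sites
    into differentially methylated regions; tests feature, expressed-gene
    and Gene Ontology over-representation against bespoke backgrounds; and
    models gene expression as a function of methylation level, genomic
    feature and their interaction. A synthetic-data module generates
    genomes, methylomes and expression counts with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    lme4,
    DESeq2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr
Config/testthat/edition: 3
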