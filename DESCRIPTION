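Package: strandsense
Title: Detecting Opposite-Strand Bias in Unstranded RNA-Seq Gene Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level read counting for stranded and unstranded RNA-seq
    libraries over exon-union gene models, producing six count types
    (stranded/unstranded, restricted or not to regions unique to each gene,
    splice-junction reads and intronic reads). From unstranded alignments
    alone it computes four alignment-derived metrics (observed versus
    expected splice-junction reads, exonic versus intronic read density,
    expression of proximal genes, exonic overlap fraction) and scores each
    gene with a decision-tree classifier for the risk that its unstranded
    count is inflated by transcription from the opposite strand. Includes
    an exact in-silico enumerator of splice-junction read probabilities and
    a seeded synthetic-data generator (annotation plus aligned reads with
    planted opposite-strand carry-over) used for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    rpart
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
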