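Package: chlorotrace
Title: Chloroplast Genome Construction and Maternal Transmission Analysis
    from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for reconstructing quadripartite chloroplast genomes
    (LSC-IRa-SSC-IRb) from whole-genome shotgun short reads and for tracing
    single-base variant transmission through a mother-father-offspring trio.
    Provides a synthetic-data generator for quadripartite genomes, mutated
    trios and Illumina-like paired-end reads; read QC analogs (end trimming,
    duplicate-pair removal, k-mer spectra and genome-size estimation); a
    k-mer seed-and-extend read mapper; a minimal de Bruijn unitig assembler
    with a multi-k sweep; QUAST-style assembly metrics and optimum-assembly
    selection; reference-guided contig merging with inverted-repeat
    detection and IRb completion from IRa; and dual-strategy (whole-genome
    comparison plus read-pileup) variant discovery with problematic-variant
    filtering, effect annotation and trio inheritance classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
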