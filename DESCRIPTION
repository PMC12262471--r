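Package: rilseqr
Title: RNA-RNA Interactome Analysis for RIL-seq and iRIL-seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein-mediated RNA-RNA interactomes from
    proximity-ligation sequencing (RIL-seq, iRIL-seq). Builds comprehensive
    bacterial genome annotations (predicted UTRs, antisense, intergenic and
    transcription-unit features), classifies mapped paired-end fragments into
    single and chimeric RNA fragments, calls statistically significant
    interacting region pairs (S-chimeras) by one-sided Fisher's exact tests
    over window pairs, assigns genes to interacting regions, quantifies
    per-feature counts with size-factor normalisation and IP/Total enrichment
    ratios, designs CRISPR-DASH sgRNA pools for ribosomal RNA depletion, and
    simulates chaperone-capture sequencing libraries with planted sRNA-mRNA
    interactions for end-to-end validation.
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
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
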