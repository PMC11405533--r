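Package: oxqc
Title: Quality Control and Comparative Analysis of Long-Read Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for assessing the quality of de novo genome assemblies and
    for downstream comparative and population-genomic summaries. Implements a
    stop-codon based estimator of residual per-base sequencing error from
    stop-free open reading frames, exon-walking verification of gene
    completeness with splice-signal and reading-frame checks, windowed
    contamination screening, nuclear-mitochondrial insertion (NUMT) scanning,
    mitochondrial circularization and coverage-tiling validation,
    multi-reference synteny-based chromosome assignment with AGP output,
    karyotype reconciliation (fusion/fission counts and fundamental number),
    GATK-style hard filtering of variant calls, heterozygosity-per-megabase
    spectra, and per-gene variant-profile tabulation. A synthetic-data
    generator produces genomes, gene models, alignments and variant sets with
    known truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
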