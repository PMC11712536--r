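Package: svradiate
Title: Radiation-Induced Structural Variant Analysis for Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genomic structural variations (SV) called
    from long-read sequencing of irradiated plants. Provides Sniffles-style
    VCF ingestion and call-level filtering, tolerance-based call-set identity,
    replicate-core (Venn) extraction and pedigree-subtraction workflows that
    isolate radiation-induced SVs, annotation of SVs by genetic element,
    chromatin state, centromeric context and rearrangement hotspots,
    deletion-junction microhomology classification into NHEJ/MMEJ/SSA repair
    signatures, seed-and-extend tracing of inserted sequences to their donor
    loci, the chi-squared and rank-sum tests used in reporting, and a
    deterministic synthetic-data generator with truth manifests for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    vcfR,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
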