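Package: bsamapr
Title: Bulked-Segregant Mapping and Downstream Target Characterization for
    Plant Mutant Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for mapping a dominant mutant locus in an
    F2 cross by bulked-segregant whole-exome analysis and characterizing its
    downstream regulatory targets. Provides seeded simulation of segregating
    F2 populations with phenotype-contrasted sequencing bulks; SNP filtering
    with conservation-checked accounting; per-locus SNP-index and
    delta-SNP-index computation with LOESS smoothing and candidate-region
    calling; recombinant counting and flanking-marker interval delimitation;
    CAPS and KASP diagnostic marker design; coding-consequence and
    splice-isoform effect prediction; qPCR (2^-ddCT) and RNA-seq (FPKM,
    fold-change + FDR) expression analysis; and DAP-seq peak-to-TSS target
    assignment with k-mer motif enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
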