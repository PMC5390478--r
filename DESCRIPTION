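Package: dswseg
Title: Somatic Copy-Number and Copy-Neutral LOH Segmentation from Paired
    Tumor/Normal Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments paired tumor/normal whole-genome sequencing data into
    regions of constant somatic copy number using a multi-scale double
    sliding-window changepoint detector over two signals: the bias-corrected
    read-depth log2 ratio per genomic bin and the mirrored, median-smoothed
    B-allele fraction (cBAF) at heterozygous SNPs.  Calls copy-neutral loss
    of heterozygosity (cnLOH) per segment and counts recurrent cnLOH regions
    across cohorts.  Includes a read-depth extraction front-end for BAM
    files, a tumor/normal simulator with ground truth (Markov-chain read
    depth, Poisson noise, binomial allele counts under normal-cell
    contamination), and evaluation statistics (breakpoint precision, recall,
    F-measure, 100-bp blockization, Jaccard similarity).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
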