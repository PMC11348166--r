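Package: gdnaclean
Title: Detection and Correction of Genomic DNA Contamination in RNA-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment quality assessment and correction of genomic DNA
    (gDNA) contamination in bulk RNA-seq experiments. Derives coordinate-collapsed
    exon, intron, intergenic, rRNA and organellar feature catalogs from an Ensembl
    GTF, assigns aligned fragments to features and genes with strand-aware modes,
    computes a battery of contamination diagnostics (read-distribution percentages
    including the intergenic read fraction IR%, expression distributions, percent
    expressed genes, pairwise correlations, distances, PCA), and corrects
    contaminated gene-level count matrices via a global fragments-per-base
    estimator, a GC-stratified loess estimator, an IR%-covariate precision-weighted
    linear model, or stranded sense-minus-antisense subtraction. Includes a
    deterministic synthetic-data generator with known contamination truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2,
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
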