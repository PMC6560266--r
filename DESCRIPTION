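Package: convergescan
Title: Windowed Selective-Sweep Scans and Convergence Testing for
    Metal-Adapted Plant Population Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for convergent local adaptation from
    population resequencing data. Reads genotypes (VCF), gene models (GFF3)
    and a reference sequence (FASTA) for paired metalliferous (M) and
    non-metalliferous (NM) populations, partitions each population contrast
    into windows of 25 consecutive SNPs, and computes a panel of
    selective-sweep metrics per window: nucleotide diversity, Watterson's
    theta, Tajima's D, Fay and Wu's H, Weir-Cockerham FST, dXY and dA,
    absolute allele-frequency difference, diversity-differentiation (DD)
    residuals, the Lewontin-Krakauer statistic, a two-dimensional
    site-frequency-spectrum composite likelihood ratio, a SweepFinder-style
    sweep CLR, and a VarLD-style linkage-disequilibrium contrast. Outlier
    windows at empirical percentiles are mapped to genes, variant effects are
    predicted from the annotation, large-effect variants at divergent
    frequencies are screened, SNPs in divergence-signature genes are scored
    for association with soil covariates by Bayes factors under an
    among-population allele-frequency covariance model, and convergence
    between contrasts and species is quantified with exact hypergeometric
    overlap tests and functional over-representation tests. A synthetic-data
    generator with planted sweeps, large-effect variants and environmental
    associations provides ground truth for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
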