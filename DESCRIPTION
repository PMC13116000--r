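Package: wssgblup
Title: Weighted Single-Step GBLUP Association Analysis for Quantitative Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Single-step genomic BLUP (ssGBLUP) association analysis for
    quantitative traits in pedigreed, partially genotyped populations.
    Builds pedigree (A), genomic (G) and unified (H) relationship matrices,
    estimates variance components by average-information REML, solves the
    animal-model mixed-model equations, back-solves SNP effects from genomic
    breeding values, and iterates SNP weighting under the unweighted,
    quadratic and non-linear A schemes. Additive genetic variance is
    partitioned into windows of 20 adjacent SNPs, recurrent windows are
    classified across weighting schemes, flanked regions are annotated
    against a GTF, and annotated gene lists are tested for over-representation
    against GMT gene sets. A gene-drop simulator with known truth supports
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, SNP, Genetics, StatisticalMethod
RoxygenNote: 7.3.3
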