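Package: xhetkin
Title: X-Chromosome Heterozygosity and Kinship Quality Control from VCF Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-level quality control for sequencing studies computed
    directly from VCF genotypes, without alignment files. Computes a
    parametric X-chromosome heterozygosity statistic (Xhet) on the
    non-pseudoautosomal interval shared across human assemblies, estimates
    pairwise kinship with the KING-robust estimator, clusters samples into
    inferred-sex groups, flags sex-label and pedigree inconsistencies, and
    scans hemizygous-expected samples for recurrent pseudo-heterozygous
    calls under variant-allele-fraction windows. Includes a pedigree-aware
    synthetic cohort simulator with ground truth for validation, and
    MultiQC-compatible report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
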