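Package: autozyg
Title: Global Autozygosity Analysis from Cohort Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes genome-wide autozygosity statistics from cohort genotype
    data: heterozygosity ratios (het over homozygous non-reference, and het over
    homozygous cohort-minor allele) and runs of homozygosity detected by a
    PLINK-style sliding-window scan. Downstream stages cover case-control
    logistic association per standard deviation, somatic mutation catalogs over
    the 96 trinucleotide substitution motifs with non-negative least-squares
    refitting to reference mutational signatures, linear signature association
    with Benjamini-Hochberg false discovery control, Cox survival models with
    maximally selected log-rank dichotomization, and DerSimonian-Laird
    random-effects meta-analysis. A seeded synthetic-cohort generator
    (Hardy-Weinberg genotypes with inbreeding, injected homozygous tracts,
    reference-allele flips, signature-mixed mutation catalogs, exponential
    survival) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    pracma,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
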