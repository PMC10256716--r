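Package: genepyscreen
Title: Genotype-First Gene Pathogenicity Screening with CNV Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotype-to-phenotype screening of a recessive disease gene
    across a sequenced cohort. Computes per-individual GenePy gene
    pathogenicity burden scores from multi-sample variant calls weighted by
    CADD deleteriousness, population allele frequency and zygosity;
    integrates whole-gene copy-number deletions into the score as additional
    biallelic loci; ranks individuals with joint (tied) ranks; classifies
    biallelic recessive genotypes (homozygous deletions, homozygous SNVs,
    compound heterozygotes) with trio-based phase resolution; tallies
    cohort-level deletion carrier counts and allele frequencies; performs
    reverse phenotyping against HPO/ICD-10-style code tables; and applies a
    five-criterion structural-damage rule engine to precomputed residue
    features. Ships a synthetic cohort generator with planted genotypes so
    the whole pipeline is testable without access-controlled data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
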