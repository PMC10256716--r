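#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Builds the default synthetic cohort: 2,000 individuals (30 trios), the
# GRCh38 NPHP1 locus, and the planted genotype composition mirroring the
# screen's findings — 10 homozygous whole-gene deletions, 8
# phenotype-positive SNV-based biallelic genotypes, 8 phenotype-negative
# biallelic genotypes, plus in-cis decoy pairs and single-heterozygote
# decoys that the classifier must exclude. Outputs land in
# results/cohort/ as the pipeline's standard file interfaces.

suppressPackageStartupMessages(library(genepyscreen))

config <- cohort_config(seed = 1L)
bundle <- generate_cohort(config)
paths <- write_cohort(bundle, "results/cohort")

cat("cohort written to results/cohort/:", length(paths), "files\n")
cat("samples:", config$n_samples, " trios:", config$n_trios,
    " sites:", nrow(bundle$sites), "\n\n")
cat("planted mechanisms:\n")
print(table(bundle$truth$mechanism))
cat("\nexpected biallelic carriers:", sum(bundle$truth$expected_biallelic),
    "(decoys:", sum(!bundle$truth$expected_biallelic), ")\n")
cat("background heterozygous deletion carriers:",
    nrow(bundle$cnv) - sum(bundle$truth$mechanism %in%
                             c("homCNV", "hetCNV", "hetCNV_plus_hetSNV")),
    "\n")
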