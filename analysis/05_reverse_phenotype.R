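#!/usr/bin/env Rscript
# Stage 5: reverse phenotyping of genotype-first findings.
#
# Joins the biallelic carriers to their phenotype codes, flags
# renal/retinal/neurological disease with age at first record, computes
# the SNV-involving share of phenotype-positive diagnoses, and compares
# the genotype-first call set against the clinically reported cases.

suppressPackageStartupMessages(library(genepyscreen))

biallelic <- read_tsv_table("results/biallelic_calls.tsv")
records <- read_phenotype_table("results/cohort/phenotypes.tsv")
code_map <- read_code_map()
flags <- flag_phenotypes(records, code_map,
                         samples = sort(unique(c(records$sample,
                                                 biallelic$sample))))
write_tsv_table(flags, "results/phenotype_flags.tsv")

snv <- snv_fraction(biallelic, flags)
cat("phenotype-positive biallelic carriers:", snv$n_phenotype_positive, "\n")
cat("of which SNV-involving:", snv$n_snv, "->", snv$percent, "%\n")

pos <- flags[flags$sample %in% biallelic$sample & flags$renal, ]
cat("age at first renal record among carriers:",
    min(pos$age_first_renal, na.rm = TRUE), "to",
    max(pos$age_first_renal, na.rm = TRUE), "years\n")

reported <- readLines("results/cohort/reported.txt")
cmp <- compare_reported(biallelic, reported)
cat("previously reported:", length(cmp$previously_reported),
    " additional genotype-first discoveries:", length(cmp$additional), "\n")

jsonlite::write_json(
  list(snv_share_percent = snv$percent,
       n_phenotype_positive = snv$n_phenotype_positive,
       n_previously_reported = length(cmp$previously_reported),
       n_additional = length(cmp$additional)),
  "results/reverse_phenotype.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
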