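# a small, fast configuration reused across tests
small_config <- function(seed = 1, ...) {
  cohort_config(n_samples = 300, n_trios = 8, n_sites = 30, seed = seed, ...)
}

test_that("invalid configurations are rejected with explicit messages", {
  expect_error(cohort_config(n_samples = 10, n_trios = 4), "n_trios")
  expect_error(cohort_config(n_samples = 35, n_trios = 3),
               "more planted carriers")
  bad <- default_planted()
  bad$trio[bad$mechanism == "compHetSNV_cis"] <- FALSE
  expect_error(cohort_config(planted = bad), "trio children")
})

test_that("same config and seed regenerate byte-identical files", {
  d1 <- make_tempdir(); d2 <- make_tempdir()
  write_cohort(generate_cohort(small_config(seed = 4)), d1)
  write_cohort(generate_cohort(small_config(seed = 4)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("every planted mechanism is realised exactly, across seeds", {
  counts <- function(seed) table(generate_cohort(small_config(seed))$truth$mechanism)
  c1 <- counts(1); c2 <- counts(31)
  expect_identical(c1, c2)   # seeds change genotypes, not planted counts
  expect_equal(unname(c1[["homCNV"]]), 10)
  b <- generate_cohort(small_config(2))
  # planted homozygous deletions: copy number 0 spanning the gene region
  hom <- b$cnv[b$cnv$copy_number == 0, ]
  expect_equal(nrow(hom), 10)
  expect_true(all(hom$start == b$config$gene_region$start &
                    hom$end == b$config$gene_region$end))
  # homozygous-deletion samples have no genotype calls inside the gene
  expect_true(all(b$gt[, hom$sample] == "./."))
})

test_that("trio genotypes are Mendelian-consistent everywhere", {
  b <- generate_cohort(small_config(9))
  ped <- b$samples[b$samples$father != "0", ]
  dos <- function(g) c("0/0" = 0, "0/1" = 1, "1/1" = 2)[g]
  for (k in seq_len(nrow(ped))) {
    child <- dos(b$gt[, ped$sample[k]])
    fa <- dos(b$gt[, ped$father[k]]); mo <- dos(b$gt[, ped$mother[k]])
    ok <- is.na(child) | is.na(fa) | is.na(mo) |
      (child >= (fa == 2) + (mo == 2) & child <= 2 - (fa == 0) - (mo == 0))
    expect_true(all(ok), label = paste("trio", ped$sample[k]))
  }
})

test_that("unplanted allele frequencies follow the configured spectrum", {
  cfg <- cohort_config(
    n_samples = 2000, n_trios = 0, n_sites = 12,
    af_spectrum = list(prop_common = 1, common_range = c(0.25, 0.25),
                       rare_log10_range = c(-5, -2.4)),
    planted = default_planted()[0, ], background_cnv = FALSE, seed = 21)
  b <- generate_cohort(cfg)
  common <- which(b$sites$role == "bg_common")
  for (s in common) {
    dos <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)[b$gt[s, ]]
    aaf <- mean(dos, na.rm = TRUE) / 2
    se <- sqrt(0.25 * 0.75 / (2 * sum(!is.na(dos))))
    expect_lt(abs(aaf - 0.25), 3 * se)
  }
})

test_that("truth table round-trips and mirrors the planted composition", {
  b <- generate_cohort(small_config(5))
  path <- tempfile(fileext = ".tsv")
  write_truth_table(b, path)
  back <- read_truth_table(path)
  expect_equal(back, b$truth)
  expect_equal(nrow(back), nrow(default_planted()))
  expect_equal(sum(back$expected_biallelic), 26)
  # empty planting yields a header-only truth file
  b0 <- generate_cohort(cohort_config(n_samples = 50, n_trios = 0,
                                      n_sites = 5,
                                      planted = default_planted()[0, ],
                                      background_cnv = FALSE, seed = 1))
  write_truth_table(b0, path)
  expect_length(readLines(path), 1)
})

test_that("written cohort parses back through the VCF reader", {
  b <- generate_cohort(small_config(6))
  d <- make_tempdir()
  write_cohort(b, d)
  calls <- read_cohort_vcf(file.path(d, "cohort.vcf"))
  expect_equal(length(calls$samples), b$config$n_samples)
  expect_equal(nrow(calls$sites), nrow(b$sites))
  # genotype dosages round-trip exactly
  dos <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[b$gt]
  expect_equal(unname(as.vector(calls$dosage)), unname(as.vector(dos)))
})
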