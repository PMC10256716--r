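test_that("per-locus contribution matches closed-form and high-precision values", {
  # exact powers of ten: homozygous rare allele
  expect_equal(variant_contribution(30, 1e-3, 1e-3), 180)
  # heterozygous carrier of the deletion-frequency allele
  expect_equal(variant_contribution(20, 1.798e-3, 1 - 1.798e-3),
               54.9198375383663, tolerance = 1e-12)
  # symmetry in the two allele frequencies
  expect_identical(variant_contribution(17, 0.2, 0.003),
                   variant_contribution(17, 0.003, 0.2))
  # term vanishes as both alleles become common
  expect_lt(variant_contribution(30, 1 - 1e-9, 1 - 1e-9), 1e-6)
  expect_error(variant_contribution(10, 0, 0.5), "strictly in")
  expect_error(variant_contribution(10, 0.5, 1), "strictly in")
  expect_error(variant_contribution(-1, 0.5, 0.5), ">= 0")
})

test_that("zygosity maps genotypes to observed allele frequencies", {
  expect_equal(zygosity_frequencies(2, 1e-3), c(1e-3, 1e-3))
  expect_equal(zygosity_frequencies(1, 1e-3), c(1e-3, 1 - 1e-3))
  expect_equal(zygosity_frequencies(0, 0.5), c(0.5, 0.5))
  expect_null(zygosity_frequencies(NA, 0.5))
  # hom-ref at a 50% site contributes a small positive term
  ff <- zygosity_frequencies(0, 0.5)
  expect_equal(variant_contribution(10, ff[1], ff[2]), -10 * log10(0.25))
  expect_gt(variant_contribution(10, ff[1], ff[2]), 0)
})

test_that("rare-allele contributions order hom-alt > het > hom-ref", {
  for (f in c(1e-4, 1e-3, 0.05, 0.49)) {
    terms <- vapply(2:0, function(d) {
      ff <- zygosity_frequencies(d, f)
      variant_contribution(25, ff[1], ff[2])
    }, numeric(1))
    expect_true(terms[1] > terms[2] && terms[2] > terms[3])
  }
})

test_that("CNV deletion terms match the oracle and defaults", {
  rule <- cnv_score_rule(40)
  expect_equal(rule$f_cnv, 1.798e-3)
  expect_equal(cnv_contribution(0, rule), 219.616825008223, tolerance = 1e-12)
  expect_equal(cnv_contribution(1, rule), 109.839675076733, tolerance = 1e-12)
  expect_warning(out <- cnv_contribution(3, rule), "duplication")
  expect_equal(out, 0)
})

test_that("CNV deleteriousness derives from the maximal stop-gain CADD", {
  sites <- data.frame(cadd_phred = c(38, 42, 47, 55),
                      consequence = c("stop_gain", "stop_gain", "stop_gain",
                                      "non_synonymous"))
  expect_equal(derive_d_cnv(sites), 47)
  expect_equal(derive_d_cnv(sites[3, ]), 47)
  none <- sites[sites$consequence != "stop_gain", ]
  expect_warning(d <- derive_d_cnv(none, fallback = 45), "fallback")
  expect_equal(d, 45)
})

test_that("gene score equals the brute-force per-locus oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n_loci <- sample(0:20, 1)
    dosage <- matrix(sample(c(0L, 1L, 2L, NA), n_loci, replace = TRUE),
                     ncol = 1, dimnames = list(NULL, "S01"))
    f <- runif(n_loci, 1e-5, 0.5)
    cadd <- runif(n_loci, 15, 47)
    calls <- annotate_calls(make_calls(dosage), f, cadd)
    has_cnv <- runif(1) < 0.5
    cnv <- if (has_cnv) data.frame(sample = "S01", contig = "chr2",
                                   start = 1L, end = 2L,
                                   copy_number = sample(0:1, 1)) else NULL
    rule <- if (has_cnv) cnv_score_rule(47) else NULL
    gs <- gene_score("S01", calls, cnv, rule)
    expected <- oracle_gene_score(
      dosage[, 1], f, cadd,
      cnv = if (has_cnv) data.frame(copy_number = cnv$copy_number,
                                    d_cnv = 47, f_cnv = 1.798e-3) else NULL)
    expect_equal(gs$S, expected, tolerance = 1e-9)
    expect_equal(gs$S, sum(gs$contributions$term), tolerance = 1e-9)
  }
})

test_that("score is additive over disjoint locus sets", {
  set.seed(7)
  dosage <- matrix(sample(0:2, 12, replace = TRUE), ncol = 1,
                   dimnames = list(NULL, "S01"))
  f <- runif(12, 1e-4, 0.4); cadd <- runif(12, 16, 40)
  calls <- annotate_calls(make_calls(dosage), f, cadd)
  half1 <- calls; half2 <- calls
  for (el in c("sites", "dosage", "gq", "dp")) {
    half1[[el]] <- calls[[el]][1:6, , drop = FALSE]
    half2[[el]] <- calls[[el]][7:12, , drop = FALSE]
  }
  expect_equal(gene_score("S01", calls)$S,
               gene_score("S01", half1)$S + gene_score("S01", half2)$S,
               tolerance = 1e-12)
})

test_that("score is monotone in deleteriousness and rarity", {
  dosage <- matrix(c(1L, 2L, 0L), ncol = 1, dimnames = list(NULL, "S01"))
  f <- c(0.01, 0.001, 0.3); cadd <- c(20, 30, 16)
  base <- gene_score("S01", annotate_calls(make_calls(dosage), f, cadd))$S
  up_d <- gene_score("S01", annotate_calls(make_calls(dosage), f,
                                           cadd + c(5, 0, 0)))$S
  expect_gt(up_d, base)
  down_f <- gene_score("S01", annotate_calls(make_calls(dosage),
                                             f * c(0.1, 1, 1), cadd))$S
  expect_gt(down_f, base)
})

test_that("linear scaling of deleteriousness scales scores and keeps ranks", {
  set.seed(11)
  dosage <- matrix(sample(0:2, 40, replace = TRUE), nrow = 8)
  f <- runif(8, 1e-4, 0.4); cadd <- runif(8, 16, 40)
  calls <- annotate_calls(make_calls(dosage), f, cadd)
  s1 <- gene_score_matrix(calls)
  calls3 <- annotate_calls(calls, f, 3 * cadd)
  s3 <- gene_score_matrix(calls3)
  expect_equal(s3$S, 3 * s1$S, tolerance = 1e-12)
  expect_identical(rank_samples(s1)$sample, rank_samples(s3)$sample)
  expect_identical(rank_samples(s1)$rank, rank_samples(s3)$rank)
})

test_that("empty variant and CNV input scores zero", {
  dosage <- matrix(integer(0), nrow = 0, ncol = 1,
                   dimnames = list(NULL, "S01"))
  calls <- annotate_calls(make_calls(dosage), numeric(0), numeric(0))
  expect_equal(gene_score("S01", calls)$S, 0)
})
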