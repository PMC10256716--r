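test_that("joint ranks share the minimum position", {
  sc <- data.frame(sample = c("a", "b", "c"), S = c(5, 5, 3))
  expect_equal(rank_samples(sc)$rank, c(1L, 1L, 3L))
  expect_equal(rank_samples(data.frame(sample = "x", S = 0))$rank, 1L)
})

test_that("a 10-way tie below 19 distinct scores sits at joint rank 20", {
  sc <- data.frame(sample = sprintf("s%02d", 1:29),
                   S = c(seq(100, 82, length.out = 19), rep(50, 10)))
  rk <- rank_samples(sc)
  expect_equal(sort(rk$rank[rk$S == 50]), rep(20L, 10))
  expect_equal(rk$rank, oracle_rank(rk$S))
})

test_that("rank agrees with the count-strictly-greater oracle", {
  set.seed(13)
  for (rep in 1:20) {
    S <- round(runif(sample(1:40, 1), 0, 50), sample(0:2, 1))
    rk <- rank_samples(data.frame(sample = seq_along(S), S = S))
    expect_equal(rk$rank, oracle_rank(rk$S))
  }
})

test_that("phase resolution matches haplotype enumeration on all 3x3 carrier configs", {
  configs <- expand.grid(f = c("A", "B", "AB"), m = c("A", "B", "AB"),
                         stringsAsFactors = FALSE)
  dos <- function(code) switch(code, A = c(1L, 0L), B = c(0L, 1L),
                               AB = c(1L, 1L))
  for (k in seq_len(nrow(configs))) {
    fa <- dos(configs$f[k]); mo <- dos(configs$m[k])
    dosage <- cbind(C1 = c(1L, 1L), F1 = fa, M1 = mo)
    calls <- make_calls(dosage)
    got <- resolve_phase("C1", calls$sites$key, trio_ped(), calls)
    want <- oracle_phase(fa, mo)
    if (want == "impossible") {
      # genotype configuration incompatible with inheritance: the variant
      # missing from both parents is flagged possible de novo
      expect_equal(got$phase, "unresolved")
      expect_true(got$possible_de_novo)
    } else {
      expect_equal(got$phase, want)
    }
  }
  # the one-carrier-parent configuration: cis is forced
  dosage <- cbind(C1 = c(1L, 1L), F1 = c(1L, 1L), M1 = c(0L, 0L))
  calls <- make_calls(dosage)
  expect_equal(resolve_phase("C1", calls$sites$key, trio_ped(), calls)$phase,
               "confirmed_cis")
  expect_equal(oracle_phase(c(1L, 1L), c(0L, 0L)), "confirmed_cis")
})

test_that("missing parents, missing genotypes and hom parents stay unresolved", {
  dosage <- cbind(C1 = c(1L, 1L), F1 = c(1L, 1L), M1 = c(0L, 0L))
  calls <- make_calls(dosage)
  # no pedigree entry
  expect_equal(resolve_phase("C1", calls$sites$key,
                             trio_ped(child = "other"), calls)$phase,
               "unresolved")
  # parent genotype missing
  dosage2 <- dosage; dosage2[1, "F1"] <- NA
  expect_equal(resolve_phase("C1", calls$sites$key, trio_ped(),
                             make_calls(dosage2))$phase, "unresolved")
  # carrier parent homozygous: ambiguous under the conservative rule
  dosage3 <- cbind(C1 = c(1L, 1L), F1 = c(2L, 1L), M1 = c(0L, 0L))
  expect_equal(resolve_phase("C1", calls$sites$key, trio_ped(),
                             make_calls(dosage3))$phase, "unresolved")
  # child listed as its own parent
  bad_ped <- trio_ped(); bad_ped$father[3] <- "C1"
  expect_error(resolve_phase("C1", calls$sites$key, bad_ped, calls),
               "own parent")
})

test_that("biallelic mechanisms classify per the decision rules", {
  samples <- c("HOMDEL", "HETDEL", "HOMSNV", "CH", "SINGLE", "NONE")
  dosage <- cbind(HOMDEL = c(NA, NA), HETDEL = c(2L, 0L),
                  HOMSNV = c(2L, 0L), CH = c(1L, 1L),
                  SINGLE = c(1L, 0L), NONE = c(0L, 0L))
  calls <- annotate_calls(make_calls(dosage), c(4e-4, 1e-3), c(24, 20))
  cnv <- data.frame(sample = c("HOMDEL", "HETDEL"), contig = "chr2",
                    start = 110123335L, end = 110205062L,
                    copy_number = c(0L, 1L), stringsAsFactors = FALSE)
  out <- classify_cohort(calls, cnv)
  get <- function(s) out[out$sample == s, ]
  expect_equal(get("HOMDEL")$mechanism, "homCNV")
  expect_equal(get("HOMDEL")$phase, "not_required")
  # hemizygous variant inside a het deletion: forced in-trans compound het
  expect_equal(get("HETDEL")$mechanism, "compHet_CNV_SNV")
  expect_equal(get("HETDEL")$phase, "confirmed_trans")
  expect_equal(get("HOMSNV")$mechanism, "homSNV")
  expect_equal(get("CH")$mechanism, "compHet_SNV_SNV")
  expect_equal(get("CH")$phase, "unresolved")   # no parental genomes
  expect_false("SINGLE" %in% out$sample)
  expect_false("NONE" %in% out$sample)
})

test_that("classification is invariant to variant presentation order", {
  dosage <- cbind(CH = c(1L, 1L, 0L), OTHER = c(0L, 1L, 2L))
  calls <- annotate_calls(make_calls(dosage), c(4e-4, 1e-3, 2e-3),
                          c(24, 20, 17))
  flip <- function(calls, ord) {
    for (el in c("sites", "dosage", "gq", "dp")) {
      calls[[el]] <- calls[[el]][ord, , drop = FALSE]
    }
    calls
  }
  a <- classify_cohort(calls, NULL)
  b <- classify_cohort(flip(calls, 3:1), NULL)
  b <- b[match(a$sample, b$sample), ]
  expect_equal(a$mechanism, b$mechanism)
  expect_equal(a$variants, b$variants)
})

test_that("confirmed-cis pairs are excluded from biallelic totals", {
  # trio: child and father share an in-cis pair; mother carries neither
  dosage <- cbind(C1 = c(1L, 1L), F1 = c(1L, 1L), M1 = c(0L, 0L))
  calls <- annotate_calls(make_calls(dosage), c(4e-4, 4e-4), c(20, 21))
  out <- classify_cohort(calls, NULL, trio_ped())
  expect_equal(out$phase[out$sample == "C1"], "confirmed_cis")
  # the transmitting father's identical pair is cis by the same evidence
  expect_equal(out$phase[out$sample == "F1"], "confirmed_cis")
  counts <- count_biallelic(out)
  expect_equal(counts$total_biallelic, 0)
  expect_equal(counts$n_excluded_cis, 2)
})

test_that("mechanism counting separates confirmed from possible", {
  calls <- data.frame(
    sample = sprintf("s%02d", 1:20),
    mechanism = c(rep("homCNV", 10), rep("homSNV", 4),
                  rep("compHet_SNV_SNV", 4), rep("compHet_CNV_SNV", 2)),
    phase = c(rep("not_required", 14), "confirmed_trans",
              rep("unresolved", 3), rep("confirmed_trans", 2)),
    variants = "", stringsAsFactors = FALSE)
  counts <- count_biallelic(calls)
  expect_equal(counts$total_biallelic, 20)
  bm <- counts$by_mechanism
  expect_equal(bm$possible[bm$mechanism == "compHet_SNV_SNV"], 3)
  expect_equal(sum(bm$confirmed) + sum(bm$possible), 20)
  empty <- count_biallelic(calls[0, ])
  expect_equal(empty$total_biallelic, 0)
  expect_equal(sum(empty$by_mechanism$confirmed), 0)
})
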