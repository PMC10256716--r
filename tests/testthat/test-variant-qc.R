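test_that("locus selection is 1-based inclusive at both bounds", {
  dosage <- matrix(1L, 3, 2)
  calls <- make_calls(dosage, pos = c(110123334L, 110123335L, 110205062L))
  kept <- select_locus(calls, nphp1_region())
  expect_equal(kept$sites$pos, c(110123335L, 110205062L))
  expect_error(select_locus(calls, genomic_interval("2", 1, 10)),
               "contig mismatch")
  empty <- make_calls(matrix(integer(0), 0, 2))
  expect_equal(nrow(select_locus(empty, nphp1_region())$sites), 0)
})

test_that("genotype filters are strict at the GQ and DP boundaries", {
  dosage <- matrix(1L, 1, 3)
  gq <- matrix(c(20, 21, 99), 1); dp <- matrix(c(30, 11, 10), 1)
  out <- apply_genotype_filters(make_calls(dosage, gq, dp))
  # GQ = 20 fails (strict), GQ 21 & DP 11 passes, DP = 10 fails (strict)
  expect_equal(as.vector(out$dosage), c(NA, 1L, NA))
  # absent GQ or DP means missing
  gq2 <- matrix(c(NA, 99, 99), 1); dp2 <- matrix(c(50, NA, 50), 1)
  out2 <- apply_genotype_filters(make_calls(dosage, gq2, dp2))
  expect_equal(as.vector(out2$dosage), c(NA, NA, 1L))
  expect_equal(dim(out2), dim(make_calls(dosage)))
})

test_that("site filters: strict mean-GQ cut, inclusive missingness ceiling", {
  n <- 10
  mk <- function(gq_val, n_missing) {
    dosage <- matrix(1L, 1, n)
    dosage[1, seq_len(n_missing)] <- NA
    make_calls(dosage, gq = matrix(gq_val, 1, n), dp = matrix(50, 1, n))
  }
  expect_equal(nrow(apply_site_filters(mk(35, 0))$calls$sites), 0)   # mean 35.0
  expect_equal(nrow(apply_site_filters(mk(36, 7))$calls$sites), 1)   # 70% miss
  got <- apply_site_filters(mk(36, 8))                                # 80% miss
  expect_equal(nrow(got$calls$sites), 0)
  expect_match(got$report$reason, "high_missingness")
  allmiss <- apply_site_filters(mk(99, 10))
  expect_equal(nrow(allmiss$calls$sites), 0)
  expect_match(allmiss$report$reason, "all_genotypes_missing")
  # mean GQ is over non-missing genotypes only
  dosage <- matrix(c(NA, rep(1L, 9)), 1)
  gq <- matrix(c(1, rep(40, 9)), 1)
  out <- apply_site_filters(make_calls(dosage, gq, matrix(50, 1, 10)))
  expect_equal(nrow(out$calls$sites), 1)
})

test_that("CADD eligibility is strict at 15 and drops unannotated sites", {
  dosage <- matrix(1L, 4, 1)
  calls <- annotate_calls(make_calls(dosage), rep(1e-3, 4),
                          c(15.56, 15.0, 18, NA))
  out <- apply_cadd_filter(calls)
  expect_equal(out$calls$sites$cadd_phred, c(15.56, 18))
  expect_equal(out$n_unannotated, 1)
  # both ends of the observed pathogenic CADD range stay eligible
  calls2 <- annotate_calls(make_calls(matrix(1L, 2, 1)), rep(1e-3, 2),
                           c(18, 28.9))
  expect_equal(nrow(apply_cadd_filter(calls2)$calls$sites), 2)
})

test_that("filtering is idempotent", {
  set.seed(5)
  dosage <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 6, 10)
  gq <- matrix(sample(5:99, 60, replace = TRUE), 6, 10)
  dp <- matrix(sample(5:60, 60, replace = TRUE), 6, 10)
  calls <- make_calls(dosage, gq, dp)
  once <- apply_site_filters(apply_genotype_filters(calls))$calls
  twice <- apply_site_filters(apply_genotype_filters(once))$calls
  expect_identical(once$sites, twice$sites)
  expect_identical(once$dosage, twice$dosage)
})

test_that("tightening any threshold never grows the retained set", {
  set.seed(6)
  dosage <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 20, 10)
  gq <- matrix(sample(5:99, 200, replace = TRUE), 20, 10)
  dp <- matrix(sample(5:60, 200, replace = TRUE), 20, 10)
  calls <- make_calls(dosage, gq, dp)
  n_retained <- function(th) {
    nrow(apply_site_filters(apply_genotype_filters(calls, th), th)$calls$sites)
  }
  base <- n_retained(qc_thresholds())
  expect_lte(n_retained(qc_thresholds(min_gq = 40)), base)
  expect_lte(n_retained(qc_thresholds(min_dp = 30)), base)
  expect_lte(n_retained(qc_thresholds(min_site_mean_gq = 60)), base)
  expect_lte(n_retained(qc_thresholds(max_missingness = 0.1)), base)
})

test_that("vectorised filters agree with a naive per-record loop", {
  set.seed(8)
  th <- qc_thresholds()
  dosage <- matrix(sample(c(0:2, NA), 300, replace = TRUE), 30, 10)
  gq <- matrix(sample(5:99, 300, replace = TRUE), 30, 10)
  dp <- matrix(sample(5:60, 300, replace = TRUE), 30, 10)
  calls <- make_calls(dosage, gq, dp)
  got <- apply_site_filters(apply_genotype_filters(calls, th), th)

  # oracle: loop every genotype and site
  dos2 <- dosage
  for (i in seq_len(nrow(dosage))) for (j in seq_len(ncol(dosage))) {
    if (is.na(gq[i, j]) || is.na(dp[i, j]) ||
        gq[i, j] <= th$min_gq || dp[i, j] <= th$min_dp) {
      dos2[i, j] <- NA
    }
  }
  keep <- logical(nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    nm <- !is.na(dos2[i, ])
    if (!any(nm)) next
    keep[i] <- mean(gq[i, nm]) > th$min_site_mean_gq &&
      mean(!nm) <= th$max_missingness
  }
  expect_identical(got$calls$sites$key, make_calls(dosage)$sites$key[keep])
  expect_identical(unname(got$calls$dosage),
                   unname(dos2[keep, , drop = FALSE]))
})
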