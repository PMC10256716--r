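# In-code fixtures shared across the suite.

# Build a variant_calls object from explicit matrices; quality defaults
# pass every filter so tests can target one rule at a time.
make_calls <- function(dosage, gq = NULL, dp = NULL,
                       contig = "chr2", pos = NULL) {
  n_site <- nrow(dosage); n_samp <- ncol(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("S%02d", seq_len(n_samp))
  }
  if (is.null(gq)) gq <- matrix(99, n_site, n_samp)
  if (is.null(dp)) dp <- matrix(50, n_site, n_samp)
  colnames(gq) <- colnames(dp) <- colnames(dosage)
  if (is.null(pos)) pos <- 110123335L + seq_len(n_site) - 1L
  sites <- data.frame(contig = rep(contig, n_site), pos = pos,
                      ref = rep("A", n_site), alt = rep("G", n_site),
                      stringsAsFactors = FALSE)
  variant_calls(sites, dosage, gq, dp)
}

# Attach annotation columns directly (bypasses the table join).
annotate_calls <- function(calls, f_alt, cadd, consequence = NA_character_) {
  calls$sites$f_alt <- f_alt
  calls$sites$cadd_phred <- cadd
  calls$sites$consequence <- rep_len(consequence, nrow(calls$sites))
  calls$sites$unannotated <- is.na(calls$sites$cadd_phred)
  calls
}

# Independent GenePy oracle: naive per-locus loop straight off the formula.
oracle_gene_score <- function(dosage, f_alt, cadd, cnv = NULL,
                              include_homref = TRUE) {
  s <- 0
  for (i in seq_along(dosage)) {
    d <- dosage[i]
    if (is.na(d)) next
    ff <- if (d == 2) c(f_alt[i], f_alt[i])
          else if (d == 1) c(f_alt[i], 1 - f_alt[i])
          else c(1 - f_alt[i], 1 - f_alt[i])
    if (d == 0 && !include_homref) next
    s <- s - cadd[i] * log10(ff[1] * ff[2])
  }
  if (!is.null(cnv)) {
    for (k in seq_len(nrow(cnv))) {
      f2 <- if (cnv$copy_number[k] == 0) cnv$f_cnv[k] else 1 - cnv$f_cnv[k]
      s <- s - cnv$d_cnv[k] * log10(cnv$f_cnv[k] * f2)
    }
  }
  s
}

# Independent joint-rank oracle: one plus the count of strictly greater.
oracle_rank <- function(S) vapply(S, function(x) 1L + sum(S > x), integer(1))

# Independent phase oracle: enumerate parental haplotype assignments
# consistent with the genotypes, transmit, and see which child phases are
# possible. Dosages are per (site A, site B); child is het at both.
oracle_phase <- function(fa, mo) {
  haps_for <- function(d) {
    # all ordered pairs of (carries A, carries B) haplotypes with given dosage
    alleles <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
    out <- list()
    for (h1 in alleles) for (h2 in alleles) {
      if (h1[1] + h2[1] == d[1] && h1[2] + h2[2] == d[2]) {
        out[[length(out) + 1L]] <- list(h1, h2)
      }
    }
    out
  }
  phases <- character(0)
  for (fh in haps_for(fa)) for (mh in haps_for(mo)) {
    for (i in 1:2) for (j in 1:2) {
      child <- rbind(fh[[i]], mh[[j]])
      if (sum(child[, 1]) == 1 && sum(child[, 2]) == 1) {
        cis <- any(child[, 1] == 1 & child[, 2] == 1)
        phases <- c(phases, if (cis) "cis" else "trans")
      }
    }
  }
  phases <- unique(phases)
  if (length(phases) == 0) "impossible"
  else if (identical(phases, "cis")) "confirmed_cis"
  else if (identical(phases, "trans")) "confirmed_trans"
  else "unresolved"
}

# Small pedigree: one trio.
trio_ped <- function(child = "C1", father = "F1", mother = "M1") {
  data.frame(family = "FAM1", individual = c(father, mother, child),
             father = c("0", "0", father), mother = c("0", "0", mother),
             sex = c(1L, 2L, 1L), affection = c(1L, 1L, 2L),
             stringsAsFactors = FALSE)
}

make_tempdir <- function() {
  d <- tempfile("cohort")
  dir.create(d)
  d
}
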