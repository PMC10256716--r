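#' Per-locus GenePy contribution
#'
#' The GenePy gene pathogenicity score for one individual is
#' \deqn{S = -\sum_i D_i \log_{10}(f_{i1} f_{i2})}
#' summing over biallelic variant loci, where `D` is the deleteriousness
#' (CADD PHRED) of the locus and `f1`, `f2` are the population frequencies
#' of the individual's two observed alleles. This function evaluates the
#' term for one locus; it is symmetric in `f1` and `f2`, non-negative
#' whenever `f1 * f2 <= 1`, and grows as the observed alleles get rarer or
#' more deleterious.
#'
#' @param D deleteriousness, CADD PHRED units, `D >= 0`.
#' @param f1,f2 population frequencies of the two observed alleles, each
#'   strictly inside (0, 1) (the annotation layer floors zeros first).
#' @return numeric term, vectorised over inputs.
#' @export
variant_contribution <- function(D, f1, f2) {
  if (any(D < 0)) stop("deleteriousness D must be >= 0")
  if (any(f1 <= 0 | f1 >= 1 | f2 <= 0 | f2 >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1); ",
         "apply the annotation frequency floor first")
  }
  -D * log10(f1 * f2)
}

#' Observed-zygosity allele frequencies
#'
#' Maps a genotype's alternate-allele dosage to the frequencies of the two
#' alleles the individual actually carries: heterozygote `(f_alt, 1 -
#' f_alt)`, homozygous alternate `(f_alt, f_alt)`, homozygous reference
#' `(1 - f_alt, 1 - f_alt)`. Missing genotypes contribute nothing.
#'
#' @param dosage 0, 1, 2 or `NA`.
#' @param f_alt population alternate-allele frequency in (0, 1).
#' @return numeric length-2 vector `(f1, f2)`, or `NULL` for missing.
#' @export
zygosity_frequencies <- function(dosage, f_alt) {
  if (is.na(dosage)) return(NULL)
  switch(as.character(dosage),
         "0" = c(1 - f_alt, 1 - f_alt),
         "1" = c(f_alt, 1 - f_alt),
         "2" = c(f_alt, f_alt),
         stop("dosage must be 0, 1, 2 or NA"))
}

#' CNV deletion scoring rule
#'
#' A whole-gene deletion enters the gene score as one extra biallelic
#' locus. Its deleteriousness `D_cnv` is taken as the maximal CADD PHRED
#' observed for a stop-gain variant in the gene's annotation set (the
#' deletion is at least as damaging as the worst premature stop); its
#' allele frequency defaults to the population structural-variant deletion
#' frequency 1.798e-3.
#'
#' @param d_cnv deleteriousness for the deletion allele.
#' @param f_cnv deletion allele frequency. Default 1.798e-3.
#' @export
cnv_score_rule <- function(d_cnv, f_cnv = 1.798e-3) {
  stopifnot(d_cnv >= 0, f_cnv > 0, f_cnv < 1)
  structure(list(d_cnv = d_cnv, f_cnv = f_cnv), class = "cnv_score_rule")
}

#' Derive the CNV deleteriousness from stop-gain annotations
#'
#' Returns the maximum CADD PHRED over variants labelled `stop_gain` in the
#' annotation set; when none is present the configured fallback is used,
#' with a warning.
#'
#' @param sites annotated site data frame (columns `cadd_phred`,
#'   `consequence`).
#' @param fallback value used when no stop-gain variant is annotated.
#' @export
derive_d_cnv <- function(sites, fallback = 45) {
  sg <- !is.na(sites$consequence) & sites$consequence == "stop_gain" &
    !is.na(sites$cadd_phred)
  if (!any(sg)) {
    warning("no stop-gain variant annotated; using fallback D_cnv = ",
            fallback)
    return(fallback)
  }
  max(sites$cadd_phred[sg])
}

#' Score contribution of a CNV deletion call
#'
#' Homozygous deletion (copy number 0): `-D_cnv * log10(f_cnv^2)`.
#' Heterozygous deletion (copy number 1): `-D_cnv * log10(f_cnv * (1 -
#' f_cnv))`. Copy numbers above 2 (duplications) are excluded with a
#' warning — only deletions are integrated.
#'
#' @param copy_number integer copy number of the call (0, 1, or >2).
#' @param rule a [cnv_score_rule()].
#' @return the score term (0 for excluded calls).
#' @export
cnv_contribution <- function(copy_number, rule) {
  stopifnot(inherits(rule, "cnv_score_rule"))
  if (copy_number > 2) {
    warning("copy number ", copy_number,
            " (duplication) excluded from scoring; deletions only")
    return(0)
  }
  if (copy_number == 0) {
    variant_contribution(rule$d_cnv, rule$f_cnv, rule$f_cnv)
  } else if (copy_number == 1) {
    variant_contribution(rule$d_cnv, rule$f_cnv, 1 - rule$f_cnv)
  } else {
    0
  }
}

#' GenePy score for one sample
#'
#' Sums per-locus contributions over the scoring-eligible variant set plus
#' any CNV deletion calls for the sample. Homozygous-reference genotypes
#' contribute their (tiny) `-D log10((1-f)^2)` term by default, taking
#' observed zygosity literally; set `include_homref = FALSE` to zero them.
#'
#' @param sample sample identifier.
#' @param eligible scoring-eligible annotated `variant_calls`.
#' @param cnv_calls CNV table (columns `sample`, `copy_number`), or `NULL`.
#' @param rule a [cnv_score_rule()] (required when `cnv_calls` supplied).
#' @param gene gene label for the output.
#' @param include_homref include homozygous-reference terms (default TRUE).
#' @return list of class `gene_score`: `sample`, `gene`, `S`,
#'   `contributions` (data frame locus/D/f1/f2/term).
#' @export
gene_score <- function(sample, eligible, cnv_calls = NULL, rule = NULL,
                       gene = "NPHP1", include_homref = TRUE) {
  stopifnot(inherits(eligible, "variant_calls"))
  loci <- character(0); Ds <- f1s <- f2s <- numeric(0)
  if (nrow(eligible$sites) > 0) {
    dos <- eligible$dosage[, sample]
    for (i in seq_along(dos)) {
      if (is.na(dos[i])) next
      if (!include_homref && dos[i] == 0) next
      ff <- zygosity_frequencies(dos[i], eligible$sites$f_alt[i])
      loci <- c(loci, eligible$sites$key[i])
      Ds <- c(Ds, eligible$sites$cadd_phred[i])
      f1s <- c(f1s, ff[1]); f2s <- c(f2s, ff[2])
    }
  }
  if (!is.null(cnv_calls) && nrow(cnv_calls) > 0) {
    mine <- cnv_calls[cnv_calls$sample == sample &
                        cnv_calls$copy_number < 2, , drop = FALSE]
    if (nrow(mine) > 0 && is.null(rule)) {
      stop("CNV calls supplied without a cnv_score_rule")
    }
    for (i in seq_len(nrow(mine))) {
      cn <- mine$copy_number[i]
      loci <- c(loci, sprintf("CNV:%s:%d-%d", mine$contig[i],
                              mine$start[i], mine$end[i]))
      Ds <- c(Ds, rule$d_cnv)
      f1s <- c(f1s, rule$f_cnv)
      f2s <- c(f2s, if (cn == 0) rule$f_cnv else 1 - rule$f_cnv)
    }
  }
  terms <- if (length(loci)) variant_contribution(Ds, f1s, f2s) else numeric(0)
  structure(list(sample = sample, gene = gene, S = sum(terms),
                 contributions = data.frame(
                   locus = loci, D = Ds, f1 = f1s, f2 = f2s, term = terms,
                   stringsAsFactors = FALSE)),
            class = "gene_score")
}

#' GenePy score matrix for a cohort
#'
#' Scores every sample in the calls object against one gene, integrating
#' CNV deletion calls, and returns a tidy score table.
#'
#' @inheritParams gene_score
#' @param calls scoring-eligible annotated `variant_calls`.
#' @return data frame: `sample`, `gene`, `S`, `n_contributing_loci`
#'   (loci with a strictly positive term).
#' @export
gene_score_matrix <- function(calls, cnv_calls = NULL, rule = NULL,
                              gene = "NPHP1", include_homref = TRUE) {
  rows <- lapply(calls$samples, function(s) {
    gs <- gene_score(s, calls, cnv_calls, rule, gene, include_homref)
    data.frame(sample = s, gene = gene, S = gs$S,
               n_contributing_loci = sum(gs$contributions$term > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
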