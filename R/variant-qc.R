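#' Quality-control thresholds
#'
#' Bundles the genotype-, site- and deleteriousness-level eligibility
#' thresholds applied before gene scoring. Genotype and site quality cuts
#' are strict inequalities (`>`), matching the conventions of the standard
#' VCF filtering tools; missingness is an inclusive ceiling (a site with
#' exactly `max_missingness` missing genotypes is retained).
#'
#' @param min_gq minimum genotype quality (retain iff GQ > this). Default 20.
#' @param min_site_mean_gq minimum site mean GQ over non-missing genotypes
#'   (strict). Default 35.
#' @param min_dp minimum read depth (strict). Default 10.
#' @param max_missingness maximum tolerated fraction of missing genotypes
#'   per site (inclusive). Default 0.70.
#' @param min_cadd_phred minimum CADD PHRED for scoring eligibility
#'   (strict). Default 15, the median CADD for canonical splice-site and
#'   non-synonymous changes.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_gq = 20, min_site_mean_gq = 35, min_dp = 10,
                          max_missingness = 0.70, min_cadd_phred = 15) {
  vals <- c(min_gq, min_site_mean_gq, min_dp, max_missingness, min_cadd_phred)
  stopifnot(all(is.finite(vals)), all(vals >= 0), max_missingness <= 1)
  structure(list(min_gq = min_gq, min_site_mean_gq = min_site_mean_gq,
                 min_dp = min_dp, max_missingness = max_missingness,
                 min_cadd_phred = min_cadd_phred),
            class = "qc_thresholds")
}

#' Genomic interval (1-based, inclusive)
#'
#' @param contig contig name (must match the VCF's naming convention).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @export
genomic_interval <- function(contig, start, end) {
  stopifnot(is.character(contig), length(contig) == 1,
            start <= end, start >= 1)
  structure(list(contig = contig, start = as.integer(start),
                 end = as.integer(end)), class = "genomic_interval")
}

#' Default NPHP1 gene locus (GRCh38)
#'
#' chr2:110,123,335-110,205,062, the interval used to extract the gene from
#' a whole-genome multi-sample VCF.
#' @export
nphp1_region <- function() genomic_interval("chr2", 110123335L, 110205062L)

#' Restrict calls to a gene locus
#'
#' Retains exactly the records whose position lies inside the interval
#' (1-based inclusive at both bounds).
#'
#' @param calls a `variant_calls` object.
#' @param interval a [genomic_interval()].
#' @export
select_locus <- function(calls, interval) {
  stopifnot(inherits(calls, "variant_calls"),
            inherits(interval, "genomic_interval"))
  if (nrow(calls$sites) > 0) {
    contigs <- unique(calls$sites$contig)
    if (!interval$contig %in% contigs) {
      stop("contig mismatch: interval is on '", interval$contig,
           "' but file has: ", paste(contigs, collapse = ", "))
    }
  }
  keep <- calls$sites$contig == interval$contig &
    calls$sites$pos >= interval$start & calls$sites$pos <= interval$end
  subset_sites(calls, keep)
}

#' Apply per-genotype quality filters
#'
#' A genotype is retained iff GQ > `min_gq` and DP > `min_dp`; genotypes
#' failing either cut, or lacking GQ or DP, are set missing. The call count
#' (matrix shape) is preserved.
#'
#' @param calls a `variant_calls` object.
#' @param thresholds a [qc_thresholds()].
#' @export
apply_genotype_filters <- function(calls, thresholds = qc_thresholds()) {
  stopifnot(inherits(calls, "variant_calls"))
  ok <- !is.na(calls$gq) & !is.na(calls$dp) &
    calls$gq > thresholds$min_gq & calls$dp > thresholds$min_dp
  calls$dosage[!ok] <- NA_integer_
  calls
}

#' Apply site-level quality filters
#'
#' A site is retained iff its mean GQ over non-missing genotypes exceeds
#' `min_site_mean_gq` and its missing fraction is at most
#' `max_missingness`. Genotype-level filtering must already have been
#' applied, so "missing" includes genotypes nulled by the GQ/DP cuts.
#' Sites with every genotype missing are excluded and reported.
#'
#' @param calls a `variant_calls` object (after [apply_genotype_filters()]).
#' @param thresholds a [qc_thresholds()].
#' @return list with `calls` (retained sites) and `report` (data frame of
#'   dropped sites and reasons).
#' @export
apply_site_filters <- function(calls, thresholds = qc_thresholds()) {
  stopifnot(inherits(calls, "variant_calls"))
  n <- length(calls$samples)
  nonmiss <- !is.na(calls$dosage)
  miss_frac <- 1 - rowSums(nonmiss) / n
  gq_masked <- calls$gq
  gq_masked[!nonmiss] <- NA
  mean_gq <- rowMeans(gq_masked, na.rm = TRUE)   # NaN when all missing

  all_missing <- rowSums(nonmiss) == 0
  fail_gq <- !all_missing & !(mean_gq > thresholds$min_site_mean_gq)
  fail_miss <- !all_missing & miss_frac > thresholds$max_missingness
  keep <- !all_missing & !fail_gq & !fail_miss

  reason <- character(0)
  dropped <- character(0)
  for (i in which(!keep)) {
    dropped <- c(dropped, calls$sites$key[i])
    reason <- c(reason, paste(c(
      if (all_missing[i]) "all_genotypes_missing",
      if (fail_gq[i]) "low_mean_gq",
      if (fail_miss[i]) "high_missingness"), collapse = ";"))
  }
  list(calls = subset_sites(calls, keep),
       report = data.frame(site = dropped, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Apply the CADD deleteriousness eligibility filter
#'
#' Retains annotated sites with CADD PHRED strictly greater than
#' `min_cadd_phred`; sites with no deleteriousness annotation are excluded
#' and counted.
#'
#' @param calls an annotated `variant_calls` object
#'   (after [join_annotations()]).
#' @param thresholds a [qc_thresholds()].
#' @return list with `calls` (the scoring-eligible set) and
#'   `n_unannotated` (count of sites dropped for missing annotation).
#' @export
apply_cadd_filter <- function(calls, thresholds = qc_thresholds()) {
  stopifnot(inherits(calls, "variant_calls"),
            !is.null(calls$sites$cadd_phred))
  unann <- calls$sites$unannotated
  keep <- !unann & calls$sites$cadd_phred > thresholds$min_cadd_phred
  list(calls = subset_sites(calls, keep), n_unannotated = sum(unann))
}

#' Run the full QC chain
#'
#' Locus selection, genotype filters, site filters, annotation join and the
#' CADD eligibility cut, in that fixed order.
#'
#' @inheritParams apply_site_filters
#' @param annotation annotation table from [read_annotation_table()].
#' @param interval gene locus; default the NPHP1 GRCh38 interval.
#' @param floor_af allele-frequency floor passed to [join_annotations()].
#' @return list with `eligible` (scoring-eligible `variant_calls`),
#'   `qc_report`, `n_unannotated`, and `filtered` (post-QC, pre-CADD calls).
#' @export
run_variant_qc <- function(calls, annotation, thresholds = qc_thresholds(),
                           interval = nphp1_region(), floor_af = 1e-5) {
  calls <- select_locus(calls, interval)
  calls <- apply_genotype_filters(calls, thresholds)
  sf <- apply_site_filters(calls, thresholds)
  annotated <- join_annotations(sf$calls, annotation, floor_af = floor_af)
  cf <- apply_cadd_filter(annotated, thresholds)
  list(eligible = cf$calls, qc_report = sf$report,
       n_unannotated = cf$n_unannotated, filtered = annotated)
}
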