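#' Read a variant annotation table
#'
#' The annotation table carries pre-extracted deleteriousness (CADD PHRED)
#' and population allele frequency for each alternate allele, keyed on
#' (contig, pos, ref, alt). Columns: `contig`, `pos`, `ref`, `alt`,
#' `cadd_phred`, `af`, and optionally `consequence` (e.g. `stop_gain`,
#' `non_synonymous`). Annotation is always consumed as a table, never
#' computed, so runs are reproducible without external services.
#'
#' @param path tab-separated file (gzip tolerated).
#' @return data frame with a `key` column added.
#' @export
read_annotation_table <- function(path) {
  ann <- read_tsv_table(path)
  required <- c("contig", "pos", "ref", "alt", "cadd_phred", "af")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  ann$key <- site_key(ann$contig, ann$pos, ann$ref, ann$alt)
  ann
}

#' Join variants to deleteriousness and allele-frequency annotation
#'
#' Exact-key join of variant sites to an annotation table. Frequencies are
#' clamped into (0, 1): a variant absent from the frequency source, or with
#' a recorded frequency of zero, receives `floor_af` so that the
#' log-frequency term of the gene score stays finite; frequencies at or
#' above 1 are clamped to `ceiling_af`. Variants absent from the
#' deleteriousness source are flagged `unannotated` (they are excluded
#' later, at the CADD eligibility filter, and counted).
#'
#' @param calls a `variant_calls` object (see [read_cohort_vcf()]).
#' @param annotation annotation data frame from [read_annotation_table()].
#' @param floor_af frequency substituted for unobserved/zero frequencies.
#'   Default `1e-5`, roughly one allele among tens of thousands of genomes.
#' @param ceiling_af upper guard keeping the reference-allele term finite.
#' @return `calls` with site columns `f_alt`, `cadd_phred`, `consequence`,
#'   `unannotated` added.
#' @export
join_annotations <- function(calls, annotation, floor_af = 1e-5,
                             ceiling_af = 1 - 1e-6) {
  stopifnot(inherits(calls, "variant_calls"))
  stopifnot(floor_af > 0, ceiling_af < 1, floor_af < ceiling_af)
  dup <- annotation$key[duplicated(annotation$key)]
  if (length(dup) > 0) {
    stop("duplicate annotation keys: ", paste(unique(dup), collapse = ", "))
  }
  idx <- match(calls$sites$key, annotation$key)
  f <- annotation$af[idx]
  f[is.na(f) | f <= 0] <- floor_af
  f[f >= 1] <- ceiling_af
  calls$sites$f_alt <- f
  calls$sites$cadd_phred <- annotation$cadd_phred[idx]
  calls$sites$consequence <-
    if ("consequence" %in% names(annotation)) annotation$consequence[idx]
    else rep(NA_character_, length(idx))
  calls$sites$unannotated <- is.na(calls$sites$cadd_phred)
  calls
}
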