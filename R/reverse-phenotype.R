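#' Read a phenotype code-to-class map
#'
#' YAML mapping each disease class (`renal`, `retinal`, `neurological`) to
#' a list of phenotype codes (HPO / ICD-10-like / custom). The package
#' ships a small illustrative default in
#' `inst/extdata/default_code_map.yaml`; real analyses swap in their own
#' query set.
#'
#' @param path YAML file; default the shipped map.
#' @return named list of character vectors.
#' @export
read_code_map <- function(path = system.file("extdata",
                                             "default_code_map.yaml",
                                             package = "genepyscreen")) {
  cm <- yaml::read_yaml(path)
  lapply(cm, function(x) as.character(unlist(x)))
}

#' Flag disease classes per sample from phenotype codes
#'
#' A class flag is true iff any of the sample's codes maps to the class;
#' the age at first record for renal and retinal disease is the minimum
#' age over the mapped codes (ages, where present, come from longitudinal
#' hospital-episode or recruitment records and so overestimate true onset).
#'
#' @param records data frame: `sample`, `code`, `system` (one of `HPO`,
#'   `ICD10`, `custom`), `age` (years, may be NA).
#' @param code_map named list from [read_code_map()].
#' @param samples optional vector of samples to report (samples with no
#'   records get all-false flags).
#' @return data frame: `sample`, `renal`, `retinal`, `neurological`,
#'   `age_first_renal`, `age_first_retinal`.
#' @export
flag_phenotypes <- function(records, code_map, samples = NULL) {
  known_systems <- c("HPO", "ICD10", "custom")
  bad <- setdiff(unique(records$system), known_systems)
  if (length(bad) > 0) {
    stop("unknown code system(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.na(records$age) & records$age < 0)) {
    stop("negative age_at_code")
  }
  samples <- samples %||% sort(unique(records$sample))
  classes <- c("renal", "retinal", "neurological")
  out <- data.frame(sample = samples, renal = FALSE, retinal = FALSE,
                    neurological = FALSE, age_first_renal = NA_real_,
                    age_first_retinal = NA_real_, stringsAsFactors = FALSE)
  for (cl in classes) {
    codes <- code_map[[cl]] %||% character(0)
    hit <- records[records$code %in% codes, , drop = FALSE]
    idx <- match(out$sample, unique(hit$sample))
    out[[cl]] <- out$sample %in% hit$sample
    if (cl %in% c("renal", "retinal")) {
      ages <- vapply(out$sample, function(s) {
        a <- hit$age[hit$sample == s]
        a <- a[!is.na(a)]
        if (length(a)) min(a) else NA_real_
      }, numeric(1))
      out[[paste0("age_first_", cl)]] <- ages
    }
  }
  out
}

#' SNV share of phenotype-positive biallelic diagnoses
#'
#' Among biallelic calls whose carrier has a renal or retinal phenotype,
#' the percentage whose mechanism involves an SNV/indel (`homSNV`,
#' `compHet_SNV_SNV`, `compHet_CNV_SNV`), rounded to the nearest integer.
#' Returns `NA` when no call is phenotype-positive.
#'
#' @param biallelic_calls table from [classify_cohort()], confirmed-cis
#'   rows already excluded or present (they are dropped here).
#' @param flags table from [flag_phenotypes()].
#' @return list: `percent`, `n_snv`, `n_phenotype_positive`.
#' @export
snv_fraction <- function(biallelic_calls, flags) {
  kept <- biallelic_calls[biallelic_calls$phase != "confirmed_cis", ,
                          drop = FALSE]
  pos_samples <- flags$sample[flags$renal | flags$retinal]
  pos <- kept[kept$sample %in% pos_samples, , drop = FALSE]
  n_pos <- nrow(pos)
  n_snv <- sum(pos$mechanism %in%
                 c("homSNV", "compHet_SNV_SNV", "compHet_CNV_SNV"))
  list(percent = if (n_pos == 0) NA_real_ else round(100 * n_snv / n_pos),
       n_snv = n_snv, n_phenotype_positive = n_pos)
}

#' Compare genotype-first calls against clinically reported cases
#'
#' Splits the biallelic call set into samples previously reported by
#' clinical centres and additional genotype-first discoveries. Reported
#' samples absent from the call set are listed with a warning.
#'
#' @param biallelic_calls table from [classify_cohort()] (confirmed-cis
#'   rows dropped here).
#' @param reported_samples character vector of reported sample IDs.
#' @return list: `previously_reported`, `additional`, `reported_not_called`
#'   (each a sorted character vector).
#' @export
compare_reported <- function(biallelic_calls, reported_samples) {
  kept <- unique(biallelic_calls$sample[
    biallelic_calls$phase != "confirmed_cis"])
  missing <- sort(setdiff(reported_samples, kept))
  if (length(missing) > 0) {
    warning("reported samples not in biallelic call set: ",
            paste(missing, collapse = ", "))
  }
  list(previously_reported = sort(intersect(kept, reported_samples)),
       additional = sort(setdiff(kept, reported_samples)),
       reported_not_called = missing)
}
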