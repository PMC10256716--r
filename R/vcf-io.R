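#' Multi-sample genotype calls
#'
#' Internal container for a block of biallelic variant calls: a site table
#' and three site-by-sample matrices (alternate-allele dosage, genotype
#' quality, read depth). Dosage is 0/1/2 with `NA` for missing. Multi-allelic
#' records are decomposed into one biallelic record per alternate allele at
#' read time, so all downstream arithmetic is per alternate allele.
#'
#' @param sites data frame with columns `contig`, `pos`, `ref`, `alt`.
#' @param dosage,gq,dp matrices, sites in rows, samples in columns.
#' @return object of class `variant_calls`.
#' @export
variant_calls <- function(sites, dosage, gq, dp) {
  stopifnot(nrow(sites) == nrow(dosage),
            identical(dim(dosage), dim(gq)),
            identical(dim(dosage), dim(dp)))
  sites$key <- site_key(sites$contig, sites$pos, sites$ref, sites$alt)
  rownames(dosage) <- rownames(gq) <- rownames(dp) <- sites$key
  structure(list(sites = sites, dosage = dosage, gq = gq, dp = dp,
                 samples = colnames(dosage)),
            class = "variant_calls")
}

#' @export
print.variant_calls <- function(x, ...) {
  cat("variant_calls:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  invisible(x)
}

#' @export
dim.variant_calls <- function(x) c(nrow(x$sites), length(x$samples))

subset_sites <- function(calls, keep) {
  calls$sites <- calls$sites[keep, , drop = FALSE]
  calls$dosage <- calls$dosage[keep, , drop = FALSE]
  calls$gq <- calls$gq[keep, , drop = FALSE]
  calls$dp <- calls$dp[keep, , drop = FALSE]
  calls
}

gt_to_dosage <- function(gt) {
  # GT strings like 0/0, 0|1, 1/1, ./.; anything containing '.' is missing
  out <- rep(NA_integer_, length(gt))
  clean <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
  alleles <- strsplit(gsub("|", "/", gt[clean], fixed = TRUE), "/", fixed = TRUE)
  out[clean] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
  out
}

#' Read a multi-sample VCF into a `variant_calls` object
#'
#' Reads a VCF 4.2 file with FORMAT fields GT:GQ:DP (via vcfR), splitting
#' multi-allelic records into biallelic ones. Genotypes carrying any
#' alternate allele other than the record under consideration are treated
#' as missing for that record.
#'
#' @param path VCF file.
#' @return a [variant_calls()] object.
#' @export
read_cohort_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))

  sites_list <- list()
  dos_list <- list()
  keep_row <- integer(0)
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      gt_i <- gt_raw[i, ]
      if (length(alts) > 1) {
        # decompose: recode allele j as 1, other alts as missing
        gt_i <- decompose_gt(gt_i, j)
      }
      sites_list[[length(sites_list) + 1L]] <- data.frame(
        contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j], stringsAsFactors = FALSE)
      dos_list[[length(dos_list) + 1L]] <- gt_to_dosage(gt_i)
      keep_row <- c(keep_row, i)
    }
  }
  sites <- do.call(rbind, sites_list)
  dosage <- do.call(rbind, dos_list)
  colnames(dosage) <- colnames(gt_raw)
  variant_calls(sites, dosage,
                gq[keep_row, , drop = FALSE],
                dp[keep_row, , drop = FALSE])
}

decompose_gt <- function(gt, allele_index) {
  a <- as.character(allele_index)
  vapply(gt, function(g) {
    if (is.na(g) || grepl(".", g, fixed = TRUE)) return(NA_character_)
    parts <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (any(!parts %in% c("0", a))) return(NA_character_)
    paste(ifelse(parts == a, "1", "0"), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a 6-column pedigree (PED) file
#'
#' Columns: family, individual, father, mother, sex, affection; `0` denotes
#' a parent not present in the cohort.
#'
#' @param path PED file (whitespace separated, no header).
#' @return data frame with the six standard columns.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "individual", "father",
                                         "mother", "sex", "affection"))
  bad <- ped$individual == ped$father | ped$individual == ped$mother
  if (any(bad)) {
    stop("pedigree inconsistency: individual listed as own parent: ",
         paste(ped$individual[bad], collapse = ", "))
  }
  ped
}
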