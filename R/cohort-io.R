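#' Write a synthetic cohort bundle to disk
#'
#' Materialises the bundle as the pipeline's external interfaces: a VCF 4.2
#' file with FORMAT `GT:GQ:DP` (`cohort.vcf`), a CNV deletion table
#' (`cnv.tsv`: sample, contig, start, end, copy_number), an annotation
#' table (`annotation.tsv`: contig, pos, ref, alt, cadd_phred, af,
#' consequence; sites simulated as absent from the annotation source are
#' omitted), a 6-column PED pedigree (`pedigree.ped`), a phenotype code
#' table (`phenotypes.tsv`), cohort labels (`cohorts.tsv`), the clinically
#' reported sample list (`reported.txt`) and the planted truth table
#' (`truth.tsv`).
#'
#' @param bundle a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             cnv = file.path(dir, "cnv.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             pedigree = file.path(dir, "pedigree.ped"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             cohorts = file.path(dir, "cohorts.tsv"),
             reported = file.path(dir, "reported.txt"),
             truth = file.path(dir, "truth.tsv"))
  write_cohort_vcf(bundle, paths["vcf"])
  write_tsv_table(bundle$cnv, paths["cnv"])
  ann <- bundle$sites[bundle$sites$annotated,
                      c("contig", "pos", "ref", "alt", "cadd_phred",
                        "af_recorded", "consequence")]
  names(ann)[names(ann) == "af_recorded"] <- "af"
  write_tsv_table(ann, paths["annotation"])
  ped <- bundle$samples[, c("family", "sample", "father", "mother",
                            "sex", "affection")]
  utils::write.table(ped, paths["pedigree"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv_table(bundle$phenotypes, paths["phenotypes"])
  write_tsv_table(bundle$samples[, c("sample", "cohort")], paths["cohorts"])
  writeLines(bundle$reported, paths["reported"])
  write_truth_table(bundle, paths["truth"])
  invisible(paths)
}

write_cohort_vcf <- function(bundle, path) {
  sites <- bundle$sites
  n_site <- nrow(sites)
  fmt <- character(n_site)
  gq_chr <- ifelse(is.na(bundle$gq), ".", as.character(bundle$gq))
  dp_chr <- ifelse(is.na(bundle$dp), ".", as.character(bundle$dp))
  body <- vapply(seq_len(n_site), function(i) {
    cells <- paste(bundle$gt[i, ], gq_chr[i, ], dp_chr[i, ], sep = ":")
    paste(c(sites$contig[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            ".", "PASS", ".", "GT:GQ:DP", cells), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=genepyscreen synthetic cohort generator",
    sprintf("##contig=<ID=%s>", unique(sites$contig)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(bundle$gt)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the planted truth table
#'
#' One row per planted sample: mechanism, true phase, phenotype class,
#' reported status, expected biallelic status and the planted site roles.
#' Round-trips losslessly through [read_truth_table()].
#'
#' @param bundle a `synthetic_cohort`.
#' @param path output TSV.
#' @export
write_truth_table <- function(bundle, path) {
  write_tsv_table(bundle$truth, path)
}

#' Read a planted truth table
#' @param path TSV written by [write_truth_table()].
#' @export
read_truth_table <- function(path) {
  tt <- read_tsv_table(path)
  tt$reported <- as.logical(tt$reported)
  tt$expected_biallelic <- as.logical(tt$expected_biallelic)
  tt
}

#' Read a CNV deletion call table
#' @param path TSV with columns sample, contig, start, end, copy_number.
#' @export
read_cnv_table <- function(path) {
  cnv <- read_tsv_table(path)
  required <- c("sample", "contig", "start", "end", "copy_number")
  missing_cols <- setdiff(required, names(cnv))
  if (length(missing_cols) > 0) {
    stop("CNV table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  cnv
}

#' Read a phenotype code table
#' @param path TSV with columns sample, code, system, age.
#' @export
read_phenotype_table <- function(path) read_tsv_table(path)
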