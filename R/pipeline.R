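#' Run the full genotype-to-phenotype pipeline
#'
#' Chains the stages in fixed order — simulate (optional) -> QC -> annotate
#' -> score -> rank -> classify -> CNV cohort summary -> reverse phenotype
#' -> structural triage (optional) — materialising every stage output as a
#' file under `out_dir` and recording a manifest with MD5 checksums, so a
#' rerun with the same inputs and seed is reproducible checksum-for-
#' checksum. Stage failures abort with the stage name.
#'
#' @param input_dir directory holding the cohort files as written by
#'   [write_cohort()] (`cohort.vcf`, `cnv.tsv`, `annotation.tsv`,
#'   `pedigree.ped`, `phenotypes.tsv`, `cohorts.tsv`, `reported.txt`), or
#'   `NULL` to simulate into `out_dir/cohort` first.
#' @param out_dir output directory.
#' @param config a [cohort_config()] used when simulating.
#' @param thresholds a [qc_thresholds()].
#' @param interval gene locus.
#' @param d_cnv_fallback CNV deleteriousness used when no stop-gain variant
#'   is annotated.
#' @param feature_table optional structural feature table path for the
#'   triage stage.
#' @param code_map phenotype code-to-class map (list or YAML path).
#' @return list with every stage result plus `manifest` (data frame of
#'   files and checksums).
#' @export
run_pipeline <- function(input_dir = NULL, out_dir,
                         config = cohort_config(),
                         thresholds = qc_thresholds(),
                         interval = nphp1_region(),
                         d_cnv_fallback = 45,
                         feature_table = NULL,
                         code_map = read_code_map()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(input_dir)) {
    input_dir <- file.path(out_dir, "cohort")
    stage("simulate", {
      bundle <- generate_cohort(config)
      write_cohort(bundle, input_dir)
    })
  }
  inputs <- file.path(input_dir, c("cohort.vcf", "cnv.tsv", "annotation.tsv",
                                   "pedigree.ped", "phenotypes.tsv",
                                   "cohorts.tsv", "reported.txt"))
  names(inputs) <- c("vcf", "cnv", "annotation", "pedigree", "phenotypes",
                     "cohorts", "reported")
  for (nm in c("vcf", "cnv", "annotation")) {
    if (!file.exists(inputs[nm])) {
      stop("pipeline stage '", if (nm == "vcf") "qc" else
           if (nm == "annotation") "annotate" else "classify",
           "' failed: missing input file ", inputs[nm], call. = FALSE)
    }
  }

  calls <- stage("qc", read_cohort_vcf(inputs["vcf"]))
  annotation <- stage("annotate", read_annotation_table(inputs["annotation"]))
  qc <- stage("qc", run_variant_qc(calls, annotation, thresholds, interval))
  write_tsv_table(qc$qc_report, file.path(out_dir, "qc_report.tsv"))

  cnv <- stage("score", read_cnv_table(inputs["cnv"]))
  rule <- stage("score", cnv_score_rule(
    suppressWarnings(derive_d_cnv(qc$eligible$sites, d_cnv_fallback))))
  scores <- stage("score", gene_score_matrix(qc$eligible, cnv, rule))
  write_tsv_table(scores, file.path(out_dir, "scores.tsv"))

  ranked <- stage("rank", rank_samples(scores))
  write_tsv_table(ranked, file.path(out_dir, "ranked.tsv"))

  pedigree <- if (file.exists(inputs["pedigree"])) {
    stage("classify", read_pedigree(inputs["pedigree"]))
  } else NULL
  biallelic <- stage("classify", classify_cohort(qc$eligible, cnv, pedigree))
  write_tsv_table(biallelic, file.path(out_dir, "biallelic_calls.tsv"))
  counts <- count_biallelic(biallelic)
  write_tsv_table(counts$by_mechanism,
                  file.path(out_dir, "biallelic_counts.tsv"))

  cohorts <- stage("summarize", read_tsv_table(inputs["cohorts"]))
  cnv_summary <- stage("summarize", summarize_cnv(cnv, cohorts, pedigree))
  write_tsv_table(cnv_summary, file.path(out_dir, "cnv_summary.tsv"))

  phen <- stage("phenotype", read_phenotype_table(inputs["phenotypes"]))
  if (is.character(code_map)) code_map <- read_code_map(code_map)
  flags <- stage("phenotype", flag_phenotypes(
    phen, code_map, samples = sort(unique(c(phen$sample, biallelic$sample)))))
  write_tsv_table(flags, file.path(out_dir, "phenotype_flags.tsv"))
  snv <- snv_fraction(biallelic, flags)
  reported <- if (file.exists(inputs["reported"])) {
    readLines(inputs["reported"])
  } else character(0)
  comparison <- compare_reported(biallelic, reported)
  report <- list(
    total_biallelic = counts$total_biallelic,
    n_excluded_cis = counts$n_excluded_cis,
    snv_share_percent = snv$percent,
    n_snv_involving = snv$n_snv,
    n_phenotype_positive = snv$n_phenotype_positive,
    n_previously_reported = length(comparison$previously_reported),
    n_additional = length(comparison$additional),
    carrier_percentage = carrier_percentage(cnv_summary))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  triage <- NULL
  if (!is.null(feature_table)) {
    triage <- stage("triage", batch_triage(read_feature_table(feature_table)))
    write_tsv_table(triage$verdicts, file.path(out_dir, "triage.tsv"))
  }

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.tsv"))
  manifest <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", outputs),
    md5 = unname(tools::md5sum(outputs)), stringsAsFactors = FALSE)
  write_tsv_table(manifest, file.path(out_dir, "manifest.tsv"))

  list(eligible = qc$eligible, qc_report = qc$qc_report, scores = scores,
       ranked = ranked, biallelic = biallelic, counts = counts,
       cnv_summary = cnv_summary, flags = flags, snv = snv,
       comparison = comparison, report = report, triage = triage,
       manifest = manifest)
}
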