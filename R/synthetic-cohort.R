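#' Default planted genotype composition
#'
#' The composition the whole pipeline is exercised against: ten homozygous
#' whole-gene deletions; eight phenotype-positive SNV-based biallelic
#' genotypes (a homozygous stop-gain sibling pair, a heterozygous-deletion
#' plus missense sibling pair, two homozygous missense carriers, one
#' trio-confirmed in-trans compound heterozygote and one possible compound
#' heterozygote); eight phenotype-negative biallelic genotypes (six
#' possible compound heterozygotes and two heterozygous deletions in-trans
#' with a missense allele); plus decoys that must never be called —
#' two in-cis variant pairs planted in trio children so phase resolution
#' can exclude them, and five lone heterozygous deletions. Eight of the
#' eighteen phenotype-positive carriers are marked as previously reported
#' by clinical centres.
#'
#' @return data frame with columns `mechanism`, `phenotype_class`, `trio`,
#'   `reported`, `sib_group`.
#' @export
default_planted <- function() {
  p <- function(mech, phen, trio = FALSE, rep = FALSE, sib = NA_integer_) {
    data.frame(mechanism = mech, phenotype_class = phen, trio = trio,
               reported = rep, sib_group = sib, stringsAsFactors = FALSE)
  }
  rbind(
    do.call(rbind, lapply(1:10, function(i)
      p("homCNV", if (i <= 8) "renal" else "retinal", rep = i <= 4))),
    p("homStopGain", "renal", rep = TRUE, sib = 1L),
    p("homStopGain", "renal", rep = TRUE, sib = 1L),
    p("hetCNV_plus_hetSNV", "renal", rep = TRUE, sib = 2L),
    p("hetCNV_plus_hetSNV", "renal", rep = TRUE, sib = 2L),
    p("homSNV", "renal"),
    p("homSNV", "retinal"),
    p("compHetSNV_trans", "renal", trio = TRUE),
    p("compHetSNV_trans", "retinal"),
    do.call(rbind, lapply(1:6, function(i) p("compHetSNV_trans", "none"))),
    p("hetCNV_plus_hetSNV", "none"),
    p("hetCNV_plus_hetSNV", "none"),
    p("compHetSNV_cis", "renal", trio = TRUE),
    p("compHetSNV_cis", "none", trio = TRUE),
    do.call(rbind, lapply(1:5, function(i) p("hetCNV", "none")))
  )
}

#' Synthetic cohort configuration
#'
#' Study conditions for the desk-scale cohort generator. Defaults emulate
#' the screened cohort at a testable size: 2,000 samples, 30 trios, the
#' GRCh38 NPHP1 locus, a frequency spectrum mixing common sites (f uniform
#' on 0.01-0.5, sub-threshold CADD) and rare sites (f = 10^U(-5, -2.4),
#' CADD straddling the eligibility cut), background heterozygous deletion
#' carriers at the published cohort carrier rate (424/78,050), and the
#' planted composition of [default_planted()].
#'
#' @param n_samples cohort size.
#' @param n_trios number of father-mother-child trios (uses `3 * n_trios`
#'   samples).
#' @param gene_region a [genomic_interval()].
#' @param n_sites background segregating sites (planted and
#'   quality-control sentinel sites are added on top).
#' @param af_spectrum list: `prop_common`, `common_range`,
#'   `rare_log10_range`.
#' @param cadd_range list: `common`, `rare` (CADD PHRED bounds).
#' @param planted planted genotype table, see [default_planted()].
#' @param background_cnv simulate unplanted heterozygous deletion carriers.
#' @param background_cnv_rate per-individual carrier probability.
#' @param seed integer RNG seed.
#' @export
cohort_config <- function(n_samples = 2000, n_trios = 30,
                          gene_region = nphp1_region(), n_sites = 56,
                          af_spectrum = list(prop_common = 0.3,
                                             common_range = c(0.01, 0.5),
                                             rare_log10_range = c(-5, -2.4)),
                          cadd_range = list(common = c(0.1, 15),
                                            rare = c(10, 35)),
                          planted = default_planted(),
                          background_cnv = TRUE,
                          background_cnv_rate = 424 / 78050,
                          seed = 1L) {
  stopifnot(n_samples > 0, n_trios >= 0, n_trios * 3 <= n_samples,
            n_sites >= 0)
  n_trio_plants <- sum(planted$trio)
  if (n_trio_plants > n_trios) {
    stop("planted composition needs ", n_trio_plants, " trio children but ",
         "only ", n_trios, " trios configured")
  }
  if (any(planted$mechanism == "compHetSNV_cis" & !planted$trio)) {
    stop("compHetSNV_cis plants must be trio children so phase is resolvable")
  }
  n_nontrio_needed <- sum(!planted$trio)
  if (n_trios * 3 + n_nontrio_needed > n_samples) {
    stop("config requests more planted carriers than available samples: ",
         "need ", n_nontrio_needed, " non-trio slots but only ",
         n_samples - n_trios * 3, " exist")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_trios = as.integer(n_trios), gene_region = gene_region,
                 n_sites = as.integer(n_sites), af_spectrum = af_spectrum,
                 cadd_range = cadd_range, planted = planted,
                 background_cnv = background_cnv,
                 background_cnv_rate = background_cnv_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Site table construction: background sites, QC sentinel sites, annotation
# edge cases, and one dedicated block of planted sites per mechanism.
build_sites <- function(config) {
  region <- config$gene_region
  planted <- config$planted
  n_common <- round(config$af_spectrum$prop_common * config$n_sites)
  n_rare <- config$n_sites - n_common

  # planted site blocks share one stop-gain site and one sibling missense
  # site; compound-het rows each get a private pair
  site_rows <- list()
  add <- function(role, af, cadd, consequence = "non_synonymous",
                  annotated = TRUE, af_recorded = NULL) {
    site_rows[[length(site_rows) + 1L]] <<- data.frame(
      role = role, af_true = af,
      af_recorded = (af_recorded %||% af), cadd_phred = cadd,
      consequence = consequence, annotated = annotated,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_common)) {
    add("bg_common", stats::runif(1, config$af_spectrum$common_range[1],
                                  config$af_spectrum$common_range[2]),
        stats::runif(1, config$cadd_range$common[1],
                     config$cadd_range$common[2]))
  }
  for (i in seq_len(n_rare)) {
    add("bg_rare", 10^stats::runif(1, config$af_spectrum$rare_log10_range[1],
                                   config$af_spectrum$rare_log10_range[2]),
        stats::runif(1, config$cadd_range$rare[1],
                     config$cadd_range$rare[2]))
  }
  add("qc_low_gq", 0.05, 20)
  add("qc_high_miss", 0.05, 20)
  add("af_zero", 5e-4, 22, af_recorded = 0)
  add("unannotated", 5e-4, NA_real_, annotated = FALSE)

  if (any(planted$mechanism == "homStopGain")) {
    add("plant_stopgain", 4e-4, 47, consequence = "stop_gain")
  }
  sib_cnv <- which(planted$mechanism == "hetCNV_plus_hetSNV" &
                     !is.na(planted$sib_group))
  if (length(sib_cnv) > 0) add("plant_cnvsnv_sib", 4e-4, 24)
  for (i in which(planted$mechanism == "hetCNV_plus_hetSNV" &
                  is.na(planted$sib_group))) {
    add(paste0("plant_cnvsnv_", i), 4e-4, stats::runif(1, 18, 28.9))
  }
  hs <- which(planted$mechanism == "homSNV")
  hom_cadd <- c(18, 28.9)
  for (j in seq_along(hs)) {
    add(paste0("plant_homsnv_", hs[j]), c(4e-3, 1e-3)[1 + (j - 1) %% 2],
        hom_cadd[1 + (j - 1) %% 2])
  }
  for (i in which(planted$mechanism %in%
                  c("compHetSNV_trans", "compHetSNV_cis"))) {
    for (ab in c("a", "b")) {
      add(paste0("plant_pair_", i, "_", ab),
          sample(c(2e-4, 4e-4, 1e-3), 1), stats::runif(1, 18, 28.9))
    }
  }
  sites <- do.call(rbind, site_rows)
  n <- nrow(sites)
  pos <- sort(sample(seq(region$start, region$end), n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  cbind(data.frame(contig = region$contig, pos = pos, ref = ref, alt = alt,
                   stringsAsFactors = FALSE), sites)
}

#' Generate a synthetic cohort bundle
#'
#' Builds a deterministic desk-scale cohort realising every planted
#' mechanism exactly: founder haplotypes are drawn per site from the
#' configured frequency spectrum, trio children inherit one haplotype from
#' each parent (so Mendelian transmission holds everywhere, including at
#' planted sites), whole-gene deletions remove haplotypes (homozygous
#' deletions emit missing genotypes; inside a heterozygous deletion the
#' retained allele is emitted homozygous-appearing, as short-read callers
#' report), and a repair pass then removes any *accidental*
#' biallelic-looking pattern from unplanted samples so the planted truth
#' table is exhaustive. Rerunning with the same config is byte-identical;
#' a different seed changes genotypes but preserves the planted counts.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` bundle: `samples`, `sites`, `gt`/`gq`/`dp`
#'   matrices, `cnv`, `phenotypes`, `reported`, `truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_samples
  planted <- config$planted
  sample_ids <- sprintf("S%04d", seq_len(n))

  ## --- pedigree & planted slot assignment -------------------------------
  fam <- paste0("F", sprintf("%04d", seq_len(n)))
  father <- mother <- rep("0", n)
  sex <- sample(1:2, n, replace = TRUE)
  trio_child <- rep(FALSE, n)
  trio_member <- rep(FALSE, n)
  for (k in seq_len(config$n_trios)) {
    idx <- (3 * (k - 1) + 1):(3 * k)      # father, mother, child
    fam[idx] <- paste0("T", sprintf("%03d", k))
    sex[idx[1]] <- 1L; sex[idx[2]] <- 2L
    father[idx[3]] <- sample_ids[idx[1]]
    mother[idx[3]] <- sample_ids[idx[2]]
    trio_child[idx[3]] <- TRUE
    trio_member[idx] <- TRUE
  }
  trio_children_idx <- which(trio_child)
  planted$slot <- rep(NA_integer_, nrow(planted))
  planted$slot[planted$trio] <- trio_children_idx[seq_len(sum(planted$trio))]
  nontrio_slots <- which(!trio_member)
  planted$slot[!planted$trio] <- nontrio_slots[seq_len(sum(!planted$trio))]
  # sibling pairs share a family
  for (g in unique(stats::na.omit(planted$sib_group))) {
    slots <- planted$slot[!is.na(planted$sib_group) & planted$sib_group == g]
    fam[slots] <- paste0("SIB", sprintf("%02d", g))
  }
  affection <- as.integer(seq_len(n) %in%
                            planted$slot[planted$phenotype_class != "none"]) + 1L
  samples <- data.frame(sample = sample_ids, family = fam, father = father,
                        mother = mother, sex = sex, affection = affection,
                        cohort = ifelse(stats::runif(n) < 62898 / 78050,
                                        "rare_disease", "cancer"),
                        stringsAsFactors = FALSE)

  ## --- sites and founder haplotypes ------------------------------------
  sites <- build_sites(config)
  ns <- nrow(sites)
  hap_of <- function(i) c(2L * i - 1L, 2L * i)
  H <- matrix(FALSE, ns, 2L * n)
  founder <- !trio_child
  for (i in which(founder)) {
    H[, hap_of(i)] <- stats::runif(2L * ns) < sites$af_true
  }
  # transmission: child hap1 from father, hap2 from mother
  tm <- matrix(NA_integer_, n, 2)
  for (i in trio_children_idx) {
    fi <- match(father[i], sample_ids); mi <- match(mother[i], sample_ids)
    tm[i, ] <- c(hap_of(fi)[sample(1:2, 1)], hap_of(mi)[sample(1:2, 1)])
  }
  retransmit <- function(H) {
    for (i in trio_children_idx) H[, hap_of(i)] <- H[, tm[i, ]]
    H
  }

  ## --- planting ---------------------------------------------------------
  prot <- matrix(FALSE, ns, 2L * n)        # protected founder-hap entries
  cnv <- data.frame(sample = character(0), copy_number = integer(0),
                    stringsAsFactors = FALSE)
  del_hap2 <- rep(FALSE, n)                 # het deletion removes hap 2
  hom_del <- rep(FALSE, n)
  site_by_role <- function(role) which(sites$role == role)
  set_hap <- function(site, hapcol, value) {
    H[site, hapcol] <<- value
    prot[site, hapcol] <<- TRUE
  }
  add_cnv <- function(i, cn) {
    cnv <<- rbind(cnv, data.frame(sample = sample_ids[i], copy_number = cn,
                                  stringsAsFactors = FALSE))
  }
  pair_count <- 0
  truth_phase <- character(nrow(planted))
  truth_vars <- character(nrow(planted))
  for (r in seq_len(nrow(planted))) {
    i <- planted$slot[r]
    mech <- planted$mechanism[r]
    if (mech == "homCNV") {
      hom_del[i] <- TRUE; add_cnv(i, 0L)
      truth_phase[r] <- "not_required"; truth_vars[r] <- "CNV"
    } else if (mech == "hetCNV") {
      del_hap2[i] <- TRUE; add_cnv(i, 1L)
      truth_phase[r] <- "not_required"; truth_vars[r] <- "CNV"
    } else if (mech == "homStopGain") {
      s <- site_by_role("plant_stopgain")
      set_hap(s, hap_of(i), TRUE)
      truth_phase[r] <- "not_required"
      truth_vars[r] <- sites$role[s]
    } else if (mech == "homSNV") {
      s <- site_by_role(paste0("plant_homsnv_", r))
      set_hap(s, hap_of(i), TRUE)
      truth_phase[r] <- "not_required"; truth_vars[r] <- sites$role[s]
    } else if (mech == "hetCNV_plus_hetSNV") {
      s <- if (!is.na(planted$sib_group[r])) site_by_role("plant_cnvsnv_sib")
           else site_by_role(paste0("plant_cnvsnv_", r))
      set_hap(s, hap_of(i)[1], TRUE)
      set_hap(s, hap_of(i)[2], FALSE)
      del_hap2[i] <- TRUE; add_cnv(i, 1L)
      truth_phase[r] <- "trans"; truth_vars[r] <- sites$role[s]
    } else if (mech %in% c("compHetSNV_trans", "compHetSNV_cis")) {
      sa <- site_by_role(paste0("plant_pair_", r, "_a"))
      sb <- site_by_role(paste0("plant_pair_", r, "_b"))
      if (planted$trio[r]) {
        fi <- match(father[i], sample_ids); mi <- match(mother[i], sample_ids)
        fh <- hap_of(fi); mh <- hap_of(mi)
        if (mech == "compHetSNV_cis") {
          # both alleles on one paternal haplotype; mother carries neither
          set_hap(sa, fh, c(TRUE, FALSE)); set_hap(sb, fh, c(TRUE, FALSE))
          set_hap(sa, mh, FALSE); set_hap(sb, mh, FALSE)
          tm[i, ] <- c(fh[1], mh[1])
        } else {
          # one allele per parent, transmitted haplotypes carry them
          set_hap(sa, fh, c(TRUE, FALSE)); set_hap(sb, fh, FALSE)
          set_hap(sb, mh, c(TRUE, FALSE)); set_hap(sa, mh, FALSE)
          tm[i, ] <- c(fh[1], mh[1])
        }
      } else {
        set_hap(sa, hap_of(i), c(TRUE, FALSE))
        set_hap(sb, hap_of(i), c(FALSE, TRUE))
      }
      truth_phase[r] <- if (mech == "compHetSNV_cis") "cis" else "trans"
      truth_vars[r] <- paste(sites$role[c(sa, sb)], collapse = ",")
      pair_count <- pair_count + 1
    } else {
      stop("unknown planted mechanism: ", mech)
    }
  }

  ## --- background heterozygous deletion carriers ------------------------
  if (isTRUE(config$background_cnv)) {
    eligible_bg <- which(!trio_member & !(seq_len(n) %in% planted$slot))
    carriers <- eligible_bg[stats::runif(length(eligible_bg)) <
                              config$background_cnv_rate]
    for (i in carriers) { del_hap2[i] <- TRUE; add_cnv(i, 1L) }
  }

  ## --- repair: no accidental biallelic pattern off the truth table ------
  eligible_site <- sites$annotated & !is.na(sites$cadd_phred) &
    sites$cadd_phred > 15 & !(sites$role %in% c("qc_low_gq", "qc_high_miss"))
  zero_allowance <- seq_len(n) %in% planted$slot |
    sample_ids %in% c(father[planted$slot], mother[planted$slot]) |
    del_hap2 | hom_del
  H <- retransmit(H)
  for (pass in 1:25) {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (hom_del[i]) next
      hcols <- hap_of(i)
      src <- if (trio_child[i]) tm[i, ] else hcols
      h1 <- H[, hcols[1]]; h2 <- if (del_hap2[i]) rep(FALSE, ns) else H[, hcols[2]]
      alt_sites <- which(eligible_site & (h1 | h2))
      allow <- if (zero_allowance[i]) 0L else 1L
      keep_het <- if (allow == 1L && length(alt_sites) > 0) alt_sites[1] else -1L
      for (s in alt_sites) {
        kept_one <- FALSE
        for (hj in 1:2) {
          col <- src[hj]
          if (hj == 2 && del_hap2[i]) next    # deleted haplotype: nothing emitted
          if (!H[s, col] || prot[s, col]) next
          if (s == keep_het && !kept_one) { kept_one <- TRUE; next }
          H[s, col] <- FALSE
          changed <- TRUE
        }
      }
    }
    H <- retransmit(H)
    if (!changed) break
  }

  ## --- genotype, GQ, DP emission ----------------------------------------
  prot_gt <- matrix(FALSE, ns, n)
  for (i in seq_len(n)) {
    src <- if (trio_child[i]) tm[i, ] else hap_of(i)
    prot_gt[, i] <- prot[, src[1]] | prot[, src[2]]
  }
  gq <- matrix(pmin(99, round(stats::rnorm(ns * n, 72, 10))), ns, n)
  low <- matrix(stats::runif(ns * n) < 0.02, ns, n)
  gq[low] <- pmax(1, round(stats::rnorm(sum(low), 12, 4)))
  dp <- matrix(stats::rpois(ns * n, 35) + 1L, ns, n)
  s_lowgq <- site_by_role("qc_low_gq")
  gq[s_lowgq, ] <- pmax(1, round(stats::rnorm(n, 28, 3)))
  s_miss <- site_by_role("qc_high_miss")
  missing80 <- stats::runif(n) < 0.8
  gq[s_miss, missing80] <- 5
  gq[s_miss, !missing80] <- 70
  for (i in which(del_hap2)) dp[, i] <- stats::rpois(ns, 18) + 1L
  gq[prot_gt] <- 99
  dp[prot_gt] <- 50

  gt <- matrix("0/0", ns, n, dimnames = list(NULL, sample_ids))
  for (i in seq_len(n)) {
    if (hom_del[i]) { gt[, i] <- "./."; next }
    hcols <- hap_of(i)
    if (del_hap2[i]) {
      gt[, i] <- ifelse(H[, hcols[1]], "1/1", "0/0")
    } else {
      d <- H[, hcols[1]] + H[, hcols[2]]
      gt[, i] <- c("0/0", "0/1", "1/1")[d + 1]
    }
  }
  gq_out <- gq; dp_out <- dp
  for (i in which(hom_del)) { gq_out[, i] <- NA; dp_out[, i] <- NA }

  ## --- CNV table, phenotypes, truth -------------------------------------
  region <- config$gene_region
  cnv_tab <- if (nrow(cnv) > 0) {
    data.frame(sample = cnv$sample, contig = region$contig,
               start = region$start, end = region$end,
               copy_number = cnv$copy_number, stringsAsFactors = FALSE)
  } else {
    data.frame(sample = character(0), contig = character(0),
               start = integer(0), end = integer(0),
               copy_number = integer(0), stringsAsFactors = FALSE)
  }

  phen <- make_phenotypes(planted, sample_ids, n)

  truth <- data.frame(sample = sample_ids[planted$slot],
                      mechanism = planted$mechanism,
                      true_phase = truth_phase,
                      phenotype_class = planted$phenotype_class,
                      reported = planted$reported,
                      expected_biallelic = !(planted$mechanism %in%
                                               c("hetCNV", "compHetSNV_cis")),
                      planted_sites = truth_vars,
                      stringsAsFactors = FALSE)

  structure(list(samples = samples, sites = sites, gt = gt, gq = gq_out,
                 dp = dp_out, cnv = cnv_tab, phenotypes = phen,
                 reported = truth$sample[truth$reported],
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

phenotype_vocab <- function() {
  list(renal = data.frame(code = c("HP:0000090", "HP:0003774", "N18.5"),
                          system = c("HPO", "HPO", "ICD10"),
                          stringsAsFactors = FALSE),
       retinal = data.frame(code = c("HP:0000556", "H35.5"),
                            system = c("HPO", "ICD10"),
                            stringsAsFactors = FALSE),
       neurological = data.frame(code = c("HP:0001263", "G93.89"),
                                 system = c("HPO", "ICD10"),
                                 stringsAsFactors = FALSE))
}

make_phenotypes <- function(planted, sample_ids, n) {
  vocab <- phenotype_vocab()
  age_range <- list(renal = c(6, 52), retinal = c(25, 54),
                    neurological = c(1, 40))
  rows <- list()
  emit <- function(sample, class) {
    v <- vocab[[class]]
    k <- sample(nrow(v), sample(1:2, 1), replace = FALSE)
    for (j in k) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = sample, code = v$code[j], system = v$system[j],
        age = round(stats::runif(1, age_range[[class]][1],
                                 age_range[[class]][2])),
        stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(nrow(planted))) {
    cl <- planted$phenotype_class[r]
    if (cl != "none") emit(sample_ids[planted$slot[r]], cl)
  }
  # sparse background phenotype noise among unplanted samples
  bg <- setdiff(seq_len(n), planted$slot)
  noisy <- bg[stats::runif(length(bg)) < 0.015]
  for (i in noisy) emit(sample_ids[i], sample(names(vocab), 1))
  if (length(rows) == 0) {
    return(data.frame(sample = character(0), code = character(0),
                      system = character(0), age = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$sample, out$code), , drop = FALSE]
}
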