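#' Joint-rank samples by descending gene score
#'
#' Ties share the minimum ("joint") rank: a sample's rank is one plus the
#' number of strictly greater scores. Display order is by descending score,
#' ties broken by sample identifier; tie-breaking never affects the rank
#' itself.
#'
#' @param scores data frame with columns `sample` and `S`.
#' @return the data frame reordered with a `rank` column added.
#' @export
rank_samples <- function(scores) {
  stopifnot(all(c("sample", "S") %in% names(scores)),
            !anyDuplicated(scores$sample))
  scores$rank <- rank(-scores$S, ties.method = "min")
  scores[order(-scores$S, scores$sample), , drop = FALSE]
}

#' Resolve compound-heterozygote phase from parental genotypes
#'
#' For a child heterozygous at two candidate sites, parental genotypes
#' decide whether the two alternate alleles lie on the same chromosome
#' (in-cis, non-diagnostic) or opposite chromosomes (in-trans):
#' both variants heterozygous in one parent and absent from the other
#' confirms cis; exactly one variant in each parent confirms trans. Any
#' other pattern — a parent unavailable or missing a genotype, a carrier
#' parent homozygous, both parents carrying both variants — is left
#' unresolved rather than guessed. A variant absent from both parents is
#' flagged possible de novo.
#'
#' @param child child sample identifier.
#' @param variant_pair character length-2 vector of site keys, both
#'   heterozygous in the child.
#' @param pedigree pedigree data frame ([read_pedigree()]).
#' @param calls `variant_calls` holding genotypes for child and parents.
#' @return list: `phase` one of `confirmed_cis`, `confirmed_trans`,
#'   `unresolved`; `possible_de_novo` logical.
#' @export
resolve_phase <- function(child, variant_pair, pedigree, calls) {
  stopifnot(length(variant_pair) == 2)
  unresolved <- list(phase = "unresolved", possible_de_novo = FALSE)
  row <- pedigree[pedigree$individual == child, , drop = FALSE]
  if (nrow(row) != 1) return(unresolved)
  if (any(row$individual == c(row$father, row$mother))) {
    stop("pedigree inconsistency: ", child, " listed as own parent")
  }
  fa <- row$father; mo <- row$mother
  if (fa %in% c("0", "") || mo %in% c("0", "") ||
      !all(c(fa, mo) %in% calls$samples)) {
    return(unresolved)
  }
  d <- calls$dosage[variant_pair, c(fa, mo), drop = FALSE]
  if (anyNA(d)) return(unresolved)

  de_novo <- any(rowSums(d > 0) == 0)
  carries <- d > 0
  # cis: one parent het at both sites, the other carrying neither
  for (p in 1:2) {
    q <- 3 - p
    if (all(d[, p] == 1) && all(d[, q] == 0)) {
      return(list(phase = "confirmed_cis", possible_de_novo = FALSE))
    }
  }
  # trans: exactly one variant in each parent, on opposite sites
  if ((carries[1, 1] && !carries[2, 1] && !carries[1, 2] && carries[2, 2]) ||
      (!carries[1, 1] && carries[2, 1] && carries[1, 2] && !carries[2, 2])) {
    return(list(phase = "confirmed_trans", possible_de_novo = de_novo))
  }
  list(phase = "unresolved", possible_de_novo = de_novo)
}

classify_one <- function(s, eligible, cnv_by_sample, pedigree) {
  call_row <- function(mechanism, phase, variants) {
    data.frame(sample = s, mechanism = mechanism, phase = phase,
               variants = paste(variants, collapse = ","),
               stringsAsFactors = FALSE)
  }
  cn <- cnv_by_sample[[s]]
  if (!is.null(cn) && cn$copy_number == 0) {
    return(call_row("homCNV", "not_required", cn$locus))
  }
  dos <- if (nrow(eligible$sites) > 0) eligible$dosage[, s] else integer(0)
  alt_idx <- which(!is.na(dos) & dos > 0)
  if (!is.null(cn) && cn$copy_number == 1) {
    # inside a heterozygous whole-gene deletion, a variant on the retained
    # haplotype is hemizygous (callers report it homozygous-appearing), so
    # any alternate allele at an eligible site forces in-trans compound het
    if (length(alt_idx) > 0) {
      return(call_row("compHet_CNV_SNV", "confirmed_trans",
                      c(cn$locus, eligible$sites$key[alt_idx])))
    }
    return(NULL)
  }
  hom_idx <- which(!is.na(dos) & dos == 2)
  if (length(hom_idx) > 0) {
    return(call_row("homSNV", "not_required", eligible$sites$key[hom_idx]))
  }
  het_idx <- which(!is.na(dos) & dos == 1)
  if (length(het_idx) >= 2) {
    keys <- sort(eligible$sites$key[het_idx])
    pairs <- utils::combn(keys, 2, simplify = FALSE)
    phases <- vapply(pairs, function(p) {
      resolve_phase(s, p, pedigree, eligible)$phase
    }, character(1))
    if (any(phases == "confirmed_trans")) {
      i <- which(phases == "confirmed_trans")[1]
      return(call_row("compHet_SNV_SNV", "confirmed_trans", pairs[[i]]))
    }
    if (all(phases == "confirmed_cis")) {
      return(call_row("compHet_SNV_SNV", "confirmed_cis", keys))
    }
    return(call_row("compHet_SNV_SNV", "unresolved", keys))
  }
  NULL
}

#' Classify biallelic candidate genotypes across a cohort
#'
#' Applies the biallelic decision rules to every sample: a homozygous
#' whole-gene deletion is `homCNV`; a heterozygous deletion plus any
#' alternate allele at a scoring-eligible site is `compHet_CNV_SNV` with
#' phase forced in-trans (hemizygosity leaves only the other chromosome); a
#' homozygous eligible SNV/indel is `homSNV`; two or more eligible
#' heterozygotes form `compHet_SNV_SNV` with phase from [resolve_phase()]
#' over all pairs (a sample is in-trans if any pair confirms trans).
#' Confirmed-cis pairs are retained in the table but excluded from
#' biallelic totals. When a trio child's pair is confirmed cis, the same
#' pair in the transmitting parent is also marked cis: the child's double
#' heterozygosity with a non-carrier other parent proves both alleles sit
#' on the one transmitted haplotype.
#'
#' @param eligible scoring-eligible annotated `variant_calls`.
#' @param cnv_calls CNV deletion table (`sample`, `contig`, `start`, `end`,
#'   `copy_number`), or `NULL`.
#' @param pedigree pedigree data frame, or `NULL` (all phases unresolved).
#' @return data frame: `sample`, `mechanism`, `phase`, `variants`.
#' @export
classify_cohort <- function(eligible, cnv_calls = NULL, pedigree = NULL) {
  stopifnot(inherits(eligible, "variant_calls"))
  if (is.null(pedigree)) {
    pedigree <- data.frame(family = character(0), individual = character(0),
                           father = character(0), mother = character(0),
                           sex = integer(0), affection = integer(0))
  }
  cnv_by_sample <- list()
  if (!is.null(cnv_calls) && nrow(cnv_calls) > 0) {
    for (i in seq_len(nrow(cnv_calls))) {
      if (cnv_calls$copy_number[i] >= 2) next
      cnv_by_sample[[cnv_calls$sample[i]]] <- list(
        copy_number = cnv_calls$copy_number[i],
        locus = sprintf("CNV:%s:%d-%d", cnv_calls$contig[i],
                        cnv_calls$start[i], cnv_calls$end[i]))
    }
  }
  rows <- lapply(eligible$samples, classify_one, eligible = eligible,
                 cnv_by_sample = cnv_by_sample, pedigree = pedigree)
  calls <- do.call(rbind, rows)
  if (is.null(calls)) {
    return(data.frame(sample = character(0), mechanism = character(0),
                      phase = character(0), variants = character(0),
                      stringsAsFactors = FALSE))
  }
  propagate_cis_to_parent(calls, pedigree)
}

# A child's confirmed-cis pair pins the pair to one transmitted parental
# haplotype; mark the identical unresolved pair in that parent as cis too.
propagate_cis_to_parent <- function(calls, pedigree) {
  cis_children <- calls$sample[calls$phase == "confirmed_cis"]
  for (child in cis_children) {
    row <- pedigree[pedigree$individual == child, , drop = FALSE]
    if (nrow(row) != 1) next
    child_vars <- calls$variants[calls$sample == child]
    for (parent in c(row$father, row$mother)) {
      hit <- calls$sample == parent & calls$phase == "unresolved" &
        calls$mechanism == "compHet_SNV_SNV" & calls$variants == child_vars
      calls$phase[hit] <- "confirmed_cis"
    }
  }
  calls
}

#' Count biallelic calls by mechanism
#'
#' Confirmed-cis pairs are excluded; unresolved compound heterozygotes are
#' retained and counted separately as "possible".
#'
#' @param calls classification table from [classify_cohort()].
#' @return list: `by_mechanism` (data frame mechanism/confirmed/possible),
#'   `total_biallelic` (all calls minus confirmed-cis),
#'   `n_excluded_cis`.
#' @export
count_biallelic <- function(calls) {
  kept <- calls[calls$phase != "confirmed_cis", , drop = FALSE]
  mechs <- c("homCNV", "homSNV", "compHet_SNV_SNV", "compHet_CNV_SNV")
  by_mech <- data.frame(
    mechanism = mechs,
    confirmed = vapply(mechs, function(m)
      sum(kept$mechanism == m & kept$phase != "unresolved"), integer(1)),
    possible = vapply(mechs, function(m)
      sum(kept$mechanism == m & kept$phase == "unresolved"), integer(1)),
    stringsAsFactors = FALSE)
  list(by_mechanism = by_mech,
       total_biallelic = nrow(kept),
       n_excluded_cis = sum(calls$phase == "confirmed_cis"))
}
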