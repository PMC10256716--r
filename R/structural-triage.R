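#' Triage thresholds for the structural-damage rules
#'
#' @param cavity_change minimum absolute cavity-volume change (expansion or
#'   contraction) flagged as damaging, in cubic angstroms; inclusive.
#'   Default 70.
#' @param max_no_distance maximum nitrogen-oxygen distance for a salt
#'   bridge, in angstroms. Default 5.0.
#' @export
triage_thresholds <- function(cavity_change = 70, max_no_distance = 5.0) {
  stopifnot(cavity_change >= 0, max_no_distance > 0)
  structure(list(cavity_change = cavity_change,
                 max_no_distance = max_no_distance),
            class = "triage_thresholds")
}

#' Residue feature record
#'
#' Precomputed structural features for one residue in either the wild-type
#' or mutant model: burial (by the modelling tool's accessibility
#' threshold), side-chain charge, side-chain hydrogen-bond partners, salt
#' bridges (partner plus N-O distance) and local cavity volume. Features
#' are consumed from tables produced by external structure modelling; this
#' module only applies the decision rules.
#'
#' @param residue_id residue identifier (e.g. `"683"`).
#' @param buried,charged logicals.
#' @param sidechain_hbonds character vector of partner residue IDs.
#' @param salt_bridges data frame with `partner` and `distance` (angstrom);
#'   distances must respect the N-O ceiling.
#' @param cavity_volume cubic angstroms.
#' @param thresholds a [triage_thresholds()] (validates bridge distances).
#' @export
residue_features <- function(residue_id, buried, charged,
                             sidechain_hbonds = character(0),
                             salt_bridges = data.frame(
                               partner = character(0), distance = numeric(0)),
                             cavity_volume = 0,
                             thresholds = triage_thresholds()) {
  if (nrow(salt_bridges) > 0 &&
      any(salt_bridges$distance > thresholds$max_no_distance)) {
    stop("salt bridge N-O distance exceeds ", thresholds$max_no_distance,
         " angstrom ceiling")
  }
  structure(list(residue_id = as.character(residue_id), buried = buried,
                 charged = charged,
                 sidechain_hbonds = as.character(sidechain_hbonds),
                 salt_bridges = salt_bridges,
                 cavity_volume = cavity_volume),
            class = "residue_features")
}

#' Assess one missense substitution against the five damage criteria
#'
#' A substitution is flagged structurally damaging when any of the
#' following holds: (1) it replaces a buried charged residue with an
#' uncharged one; (2) it disrupts every side-chain hydrogen bond formed by
#' the wild type; (3) as (2), additionally requiring the wild-type residue
#' to be buried; (4) it expands or contracts the cavity volume by at least
#' the cavity threshold (70 cubic angstroms by default, inclusive); (5) it
#' breaks a salt bridge formed by a buried wild-type residue.
#'
#' @param label mutation label (e.g. `"R683W"`).
#' @param wt,mut [residue_features()] for the same residue position in the
#'   wild-type and mutant models.
#' @param thresholds a [triage_thresholds()].
#' @return list of class `triage_verdict`: `label`, `criteria` (named
#'   logical c1..c5), `damaging`, `delta_cavity`.
#' @export
assess_mutation <- function(label, wt, mut, thresholds = triage_thresholds()) {
  stopifnot(inherits(wt, "residue_features"),
            inherits(mut, "residue_features"))
  if (!identical(wt$residue_id, mut$residue_id)) {
    stop("wild-type and mutant records describe different residues: ",
         wt$residue_id, " vs ", mut$residue_id)
  }
  c1 <- wt$buried && wt$charged && !mut$charged
  lost_all_hbonds <- length(wt$sidechain_hbonds) > 0 &&
    !any(wt$sidechain_hbonds %in% mut$sidechain_hbonds)
  c2 <- lost_all_hbonds
  c3 <- lost_all_hbonds && wt$buried
  delta <- mut$cavity_volume - wt$cavity_volume
  c4 <- abs(delta) >= thresholds$cavity_change
  c5 <- wt$buried && nrow(wt$salt_bridges) > 0 &&
    any(!(wt$salt_bridges$partner %in% mut$salt_bridges$partner))
  criteria <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5)
  structure(list(label = label, criteria = criteria,
                 damaging = any(criteria), delta_cavity = delta),
            class = "triage_verdict")
}

#' Read a wild-type/mutant residue feature table
#'
#' Tab-separated columns: `mutation`, `residue_id`, `side` (`wt`/`mut`),
#' `buried`, `charged`, `hbond_partners` (semicolon list, empty allowed),
#' `salt_bridges` (semicolon list of `partner:distance`), `cavity_volume`.
#'
#' @param path file path.
#' @param thresholds a [triage_thresholds()].
#' @return named list of `list(wt =, mut =)` feature pairs, one per
#'   mutation.
#' @export
read_feature_table <- function(path, thresholds = triage_thresholds()) {
  tab <- read_tsv_table(path)
  parse_list <- function(x) {
    if (is.na(x) || x == "" || x == ".") character(0)
    else strsplit(x, ";", fixed = TRUE)[[1]]
  }
  parse_bridges <- function(x) {
    items <- parse_list(x)
    if (length(items) == 0) {
      return(data.frame(partner = character(0), distance = numeric(0)))
    }
    parts <- strsplit(items, ":", fixed = TRUE)
    data.frame(partner = vapply(parts, `[`, "", 1),
               distance = as.numeric(vapply(parts, `[`, "", 2)),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (m in unique(tab$mutation)) {
    rows <- tab[tab$mutation == m, , drop = FALSE]
    pair <- list()
    for (side in c("wt", "mut")) {
      r <- rows[rows$side == side, , drop = FALSE]
      if (nrow(r) != 1) {
        warning("skipping malformed rows for mutation ", m,
                ": expected one '", side, "' row, found ", nrow(r))
        pair <- NULL
        break
      }
      pair[[side]] <- residue_features(
        r$residue_id, as.logical(r$buried), as.logical(r$charged),
        parse_list(r$hbond_partners), parse_bridges(r$salt_bridges),
        r$cavity_volume, thresholds)
    }
    if (!is.null(pair)) out[[m]] <- pair
  }
  out
}

#' Triage a batch of mutations
#'
#' @param features named list from [read_feature_table()].
#' @param thresholds a [triage_thresholds()].
#' @return list: `verdicts` (data frame label/c1..c5/damaging/
#'   delta_cavity) and `summary` (`n_damaging`, `n_not_damaging`).
#' @export
batch_triage <- function(features, thresholds = triage_thresholds()) {
  rows <- lapply(names(features), function(m) {
    v <- assess_mutation(m, features[[m]]$wt, features[[m]]$mut, thresholds)
    data.frame(label = v$label, t(as.data.frame(v$criteria)),
               damaging = v$damaging, delta_cavity = v$delta_cavity,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  verdicts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), c1 = logical(0), c2 = logical(0),
               c3 = logical(0), c4 = logical(0), c5 = logical(0),
               damaging = logical(0), delta_cavity = numeric(0))
  list(verdicts = verdicts,
       summary = list(n_damaging = sum(verdicts$damaging),
                      n_not_damaging = sum(!verdicts$damaging)))
}
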