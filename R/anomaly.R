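# Screen for non-diploid offspring from marker genotypes, assign the
# contributing parent and mechanism, and apply the per-chromosome exclusion
# rule to transmission records.
#
# Length genotypes carry no dosage, so only abnormalities that change the
# set of observable allele lengths are detectable: calls therefore carry the
# count of informative markers, and isodisomic MII errors through homozygous
# parents are invisible by construction.

#' Detect chromosomal abnormalities in offspring genotypes
#'
#' Per offspring, markers showing more than two distinct alleles imply three
#' or more chromosome copies. Default decision rules: `tetraploidy` when at
#' least `min_chrom` chromosomes show a four-allele marker; `triploidy` when
#' at least `min_chrom` chromosomes show three alleles; `trisomy` when
#' exactly one chromosome does; `haploidy` when every genotyped marker shows
#' a single allele, all attributable to one parent; `monosomy` when the
#' markers of one chromosome show single-parent-only inheritance against a
#' heterozygous-partner expectation (requires `min_markers_monosomy` markers
#' on the chromosome to separate monosomy from simple dropout).
#'
#' Monosomy is only called when every marker of the chromosome is
#' inconsistent with the missing parent (single allelic dropouts mimic the
#' pattern at one marker, so a one-marker signal is never called).
#'
#' @param ds A validated `drive_dataset`.
#' @param min_chrom Chromosomes with a multi-allele marker required for a
#'   ploidy-level call (default 2).
#' @param min_markers_monosomy Minimum markers per chromosome for a monosomy
#'   call (default 2).
#' @return Data frame of class `anomaly_calls`: `offspring_id`, `type`,
#'   `chromosomes` (comma-separated, or `"all"`), `contributing_parent`
#'   (`"dam"`, `"sire"`, `"unknown"`), `mechanism` (filled by
#'   [classify_mechanism()]), `n_informative_markers`.
#' @export
detect_anomalies <- function(ds, min_chrom = 2L, min_markers_monosomy = 2L) {
  ped <- ds$individuals
  g <- ds$genotypes
  mk <- ds$markers
  empty <- data.frame(offspring_id = character(), type = character(),
                      chromosomes = character(),
                      contributing_parent = character(),
                      mechanism = character(),
                      n_informative_markers = integer(),
                      stringsAsFactors = FALSE)
  off <- ped[!is.na(ped$dam_id) & !is.na(ped$sire_id), , drop = FALSE]
  if (!nrow(off)) {
    out <- empty
    class(out) <- c("anomaly_calls", "data.frame")
    return(out)
  }
  gkey <- paste(g$individual_id, g$marker_id)
  chrom_of <- mk$chromosome[match(g$marker_id, mk$marker_id)]
  calls <- list()
  # distinct observable alleles per genotype; extra slots a3/a4 are distinct
  # additions by convention
  n_distinct <- (g$a1 > 0L) + (g$a2 > 0L & g$a2 != g$a1) +
    (!is.na(g$a3)) + (!is.na(g$a4))
  rows_by_ind <- split(seq_len(nrow(g)), g$individual_id)
  # per genotype row, the row index of each parent's genotype at that marker
  dam_of_row <- ped$dam_id[match(g$individual_id, ped$individual_id)]
  sire_of_row <- ped$sire_id[match(g$individual_id, ped$individual_id)]
  dam_row <- match(paste(dam_of_row, g$marker_id), gkey)
  sire_row <- match(paste(sire_of_row, g$marker_id), gkey)
  prows <- list(dam = dam_row, sire = sire_row)
  for (oi in seq_len(nrow(off))) {
    kid <- off$individual_id[oi]
    rows <- rows_by_ind[[kid]]
    if (is.null(rows)) next
    dam <- off$dam_id[oi]; sire <- off$sire_id[oi]
    nd <- n_distinct[rows]
    chroms <- chrom_of[rows]
    markers <- g$marker_id[rows]
    chr3 <- unique(chroms[nd >= 3])
    chr4 <- unique(chroms[nd >= 4])
    if (length(chr4) >= min_chrom) {
      calls[[length(calls) + 1L]] <- list(kid, "tetraploidy", "all",
                                          dam, sire, rows, chr3)
    } else if (length(chr3) >= min_chrom) {
      calls[[length(calls) + 1L]] <- list(kid, "triploidy", "all",
                                          dam, sire, rows, chr3)
    } else if (length(chr3) == 1L) {
      calls[[length(calls) + 1L]] <- list(kid, "trisomy", chr3,
                                          dam, sire, rows, chr3)
    } else if (all(nd == 1L)) {
      # all single-allele: haploidy when one parent explains every marker and
      # the other fails at two or more
      attrib <- attribution_counts(g, rows, prows)
      if (attrib$dam_all && attrib$sire_fail >= 2L) {
        calls[[length(calls) + 1L]] <- list(kid, "haploidy", "all",
                                            dam, sire, rows, character())
      } else if (attrib$sire_all && attrib$dam_fail >= 2L) {
        calls[[length(calls) + 1L]] <- list(kid, "haploidy", "all",
                                            dam, sire, rows, character())
      }
    } else {
      # monosomy: a whole chromosome single-allele, fully attributable to one
      # parent and inconsistent with the other parent at EVERY marker (a
      # single-marker signal is indistinguishable from allelic dropout)
      for (ch in unique(chroms)) {
        sel <- chroms == ch
        nm <- sum(sel)
        if (nm < min_markers_monosomy) next
        if (!all(nd[sel] == 1L)) next
        attrib <- attribution_counts(g, rows[sel], prows)
        if ((attrib$dam_all && attrib$sire_fail == nm) ||
            (attrib$sire_all && attrib$dam_fail == nm)) {
          calls[[length(calls) + 1L]] <- list(kid, "monosomy", ch,
                                              dam, sire, rows[sel], character())
        }
      }
    }
  }
  if (!length(calls)) {
    out <- empty
    class(out) <- c("anomaly_calls", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(calls, function(cl) {
    kid <- cl[[1]]; type <- cl[[2]]; chroms <- cl[[3]]
    dam <- cl[[4]]; sire <- cl[[5]]; rows <- cl[[6]]; chr3 <- cl[[7]]
    cp <- "unknown"
    ninf <- 0L
    if (type %in% c("triploidy", "tetraploidy", "trisomy")) {
      att <- extra_set_attribution(g, rows, chrom_of[rows], chr3, prows)
      cp <- att$parent
      ninf <- att$n_informative
    } else if (type %in% c("haploidy", "monosomy")) {
      att <- attribution_counts(g, rows, prows)
      if (type == "haploidy") {
        cp <- if (att$dam_all && att$sire_fail >= 2L) "dam" else "sire"
      } else {
        # the contributing (abnormal, nullisomic) gamete came from the parent
        # that is NOT represented
        cp <- if (att$dam_all && att$sire_fail >= 1L) "sire" else "dam"
      }
      ninf <- max(att$dam_fail, att$sire_fail)
    }
    data.frame(offspring_id = kid, type = type,
               chromosomes = paste(chroms, collapse = ","),
               contributing_parent = cp, mechanism = "unknown",
               n_informative_markers = ninf, stringsAsFactors = FALSE)
  }))
  class(out) <- c("anomaly_calls", "data.frame")
  out
}

# Can each parent alone explain all single-allele markers of these rows?
# `prows` carries precomputed parent genotype-row indices per offspring row.
attribution_counts <- function(g, rows, prows) {
  dam_ok <- sire_ok <- logical(length(rows))
  for (j in seq_along(rows)) {
    al <- g$a1[rows[j]]
    for (side in c("dam", "sire")) {
      pr <- prows[[side]][rows[j]]
      ok <- if (is.na(pr)) NA else {
        ps <- c(g$a1[pr], g$a2[pr], g$a3[pr], g$a4[pr])
        # a NULL or W placeholder in the parent can stand behind any single
        # observable allele (the partner supplied it)
        al %in% ps || any(ps <= 0L, na.rm = TRUE)
      }
      if (side == "dam") dam_ok[j] <- isTRUE(ok) || is.na(ok)
      else sire_ok[j] <- isTRUE(ok) || is.na(ok)
    }
  }
  list(dam_all = all(dam_ok), sire_all = all(sire_ok),
       dam_fail = sum(!dam_ok), sire_fail = sum(!sire_ok))
}

# Which parent contributed the extra allele(s) at multi-allele markers?
extra_set_attribution <- function(g, rows, chroms, affected, prows) {
  votes <- c(dam = 0L, sire = 0L)
  ninf <- 0L
  for (j in seq_along(rows)) {
    if (length(affected) && !chroms[j] %in% affected) next
    al <- c(g$a1[rows[j]], g$a2[rows[j]], g$a3[rows[j]], g$a4[rows[j]])
    al <- unique(al[!is.na(al) & al > 0])
    if (length(al) < 3L) next
    for (side in c("dam", "sire")) {
      pr <- prows[[side]][rows[j]]
      orr <- prows[[if (side == "dam") "sire" else "dam"]][rows[j]]
      if (is.na(pr) || is.na(orr)) next
      ps <- unique(c(g$a1[pr], g$a2[pr]))
      os <- c(g$a1[orr], g$a2[orr], NULL_ALLELE)
      # parent supplies two of the alleles, the partner covers the rest
      if (sum(al %in% ps) >= 2L && all(al[!al %in% ps] %in% os)) {
        votes[side] <- votes[side] + 1L
        ninf <- ninf + 1L
      }
    }
  }
  parent <- if (votes["dam"] > votes["sire"]) "dam"
  else if (votes["sire"] > votes["dam"]) "sire"
  else "unknown"
  list(parent = parent, n_informative = ninf)
}

#' Assign the most likely mechanism to anomaly calls
#'
#' For triploidy/tetraploidy/trisomy calls with a known contributing parent,
#' inspects centromere-linked markers of the affected chromosomes at which
#' that parent is heterozygous: a doubled contribution showing both parental
#' homologs points to meiosis-I nondisjunction, a doubled single allele to
#' meiosis II, and a paternal extra set carrying both homologs at only about
#' half the informative chromosomes (independent segregation of two sperm)
#' to polyspermy.
#'
#' @param calls `anomaly_calls` from [detect_anomalies()].
#' @param ds The dataset.
#' @param frac_mi Minimum fraction of informative centromeric markers showing
#'   both homologs for an MI call (default 0.9).
#' @param frac_mii Maximum fraction for an MII call (default 0.1).
#' @param poly_range Fraction window for a polyspermy call on paternal sets
#'   (default `c(0.25, 0.75)`).
#' @return `calls` with the `mechanism` column updated.
#' @export
classify_mechanism <- function(calls, ds, frac_mi = 0.9, frac_mii = 0.1,
                               poly_range = c(0.25, 0.75)) {
  if (!nrow(calls)) return(calls)
  g <- ds$genotypes
  mk <- ds$markers
  gkey <- paste(g$individual_id, g$marker_id)
  ped <- ds$individuals
  cen_mk <- mk[mk$position_class == "centromeric" & !mk$is_z_linked, ,
               drop = FALSE]
  for (i in seq_len(nrow(calls))) {
    if (!calls$type[i] %in% c("triploidy", "tetraploidy", "trisomy")) next
    if (calls$contributing_parent[i] == "unknown") next
    kid <- calls$offspring_id[i]
    pid <- if (calls$contributing_parent[i] == "dam") {
      ped$dam_id[match(kid, ped$individual_id)]
    } else {
      ped$sire_id[match(kid, ped$individual_id)]
    }
    target <- if (calls$chromosomes[i] == "all") cen_mk else
      cen_mk[cen_mk$chromosome %in% strsplit(calls$chromosomes[i], ",")[[1]], ,
             drop = FALSE]
    n_inf <- 0L
    n_both <- 0L
    for (j in seq_len(nrow(target))) {
      pr <- match(paste(pid, target$marker_id[j]), gkey)
      kr <- match(paste(kid, target$marker_id[j]), gkey)
      if (is.na(pr) || is.na(kr)) next
      ps <- c(g$a1[pr], g$a2[pr])
      if (ps[1] == ps[2] || any(ps <= 0)) next # parent uninformative here
      kal <- unique(c(g$a1[kr], g$a2[kr], g$a3[kr], g$a4[kr]))
      kal <- kal[!is.na(kal) & kal > 0]
      n_inf <- n_inf + 1L
      if (all(ps %in% kal)) n_both <- n_both + 1L
    }
    calls$n_informative_markers[i] <- n_inf
    if (n_inf == 0L) next
    frac <- n_both / n_inf
    mech <- "unknown"
    if (frac >= frac_mi) mech <- "MI_nondisjunction"
    else if (frac <= frac_mii) mech <- "MII_nondisjunction"
    else if (calls$contributing_parent[i] == "sire" &&
             frac >= poly_range[1] && frac <= poly_range[2]) {
      mech <- "polyspermy"
    }
    calls$mechanism[i] <- mech
  }
  calls
}

#' Drop transmission records on chromosomes affected by an abnormality
#'
#' A transmission record is removed when its offspring carries an anomaly
#' call on that chromosome and the parent contributing the abnormal
#' chromosome set is a hybrid or backcrossed individual (whose transmissions
#' are the quantity of interest). Calls with an unknown contributor are
#' excluded conservatively whenever either parent is a hybrid.
#'
#' @param records Transmission records.
#' @param calls `anomaly_calls`.
#' @param hybrid_parent_ids Ids of hybrid/backcross individuals (F1, BC1).
#' @param ds Dataset (to resolve `contributing_parent` sides to ids).
#' @return The filtered records.
#' @export
apply_exclusions <- function(records, calls, hybrid_parent_ids, ds) {
  if (!nrow(calls) || !nrow(records)) return(records)
  ped <- ds$individuals
  all_chroms <- unique(ds$markers$chromosome)
  drop <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(calls))) {
    kid <- calls$offspring_id[i]
    chroms <- if (calls$chromosomes[i] == "all") all_chroms else
      strsplit(calls$chromosomes[i], ",")[[1]]
    dam <- ped$dam_id[match(kid, ped$individual_id)]
    sire <- ped$sire_id[match(kid, ped$individual_id)]
    contrib <- switch(calls$contributing_parent[i],
                      dam = dam, sire = sire, NA_character_)
    hybrid_contrib <- if (is.na(contrib)) {
      any(c(dam, sire) %in% hybrid_parent_ids)
    } else {
      contrib %in% hybrid_parent_ids
    }
    if (!hybrid_contrib) next
    drop <- drop | (records$offspring_id == kid &
                      records$chromosome %in% chroms)
  }
  records[!drop, , drop = FALSE]
}
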