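# Genotype-level nuisance processes: null alleles (allelic dropout) and
# chromosomal abnormalities. Infertile eggs and survivorship fates are part
# of the breeding-design loop in simulate_cross(); the processes here edit
# genotypes after the fact and log every injected event in the truth log.

#' Inject genotype-level nuisance processes into a simulated dataset
#'
#' Applies chromosomal abnormalities (tetraploidy, triploidy, haploidy,
#' trisomy, monosomy with an MI-nondisjunction / MII-nondisjunction /
#' polyspermy mechanism mix) and null-allele dropout to a simulated dataset.
#' MI nondisjunction contributes both parental homologs (visible at
#' centromere-linked markers of a heterozygous parent), MII nondisjunction
#' contributes two copies of one chromatid (invisible without dosage),
#' polyspermy contributes a second independent paternal gamete. Null alleles
#' mask one allele of a genotype, turning heterozygotes into apparent
#' homozygotes (a hemizygous ZW female loses her only observable allele and
#' the genotype record is dropped). Allele add/remove edits are restricted to
#' autosomes.
#'
#' @param ds Simulated `drive_dataset` (pre-nuisance).
#' @param truth The accompanying `truth_log`.
#' @param cfg The [cross_config()] holding the rates.
#' @param seed Seed for the nuisance stream.
#' @return A `cross_sim`-shaped list with updated `dataset` and `truth`.
#' @export
inject_nuisance <- function(ds, truth, cfg, seed = 1L) {
  rates <- cfg$abnormality_rates
  if (any(rates < 0 | rates > 1) || cfg$null_allele_rate < 0 ||
      cfg$null_allele_rate > 1) {
    stop_fmt("configuration error: nuisance rates must lie in [0, 1]")
  }
  set.seed(seed)
  g <- ds$genotypes
  mk <- ds$markers
  ped <- ds$individuals
  gkey <- paste(g$individual_id, g$marker_id)
  auto_mk <- mk[!mk$is_z_linked, , drop = FALSE]
  events <- list()

  # transmitted-allele lookup from the truth log
  tm <- truth$meioses
  tkey <- paste(tm$offspring_id, tm$parent_id, tm$chromosome)
  trans_allele <- function(off, par, chrom, class) {
    i <- match(paste(off, par, chrom), tkey)
    if (class == "centromeric") tm$cen_allele[i] else tm$dist_allele[i]
  }

  drop_rows <- integer()
  add_allele <- function(row, allele) {
    if (is.na(allele) || allele <= 0) return(invisible())
    cur <- c(g$a1[row], g$a2[row], g$a3[row], g$a4[row])
    if (allele %in% cur) return(invisible())
    slot <- which(is.na(cur))[1]
    if (!is.na(slot)) g[[paste0("a", slot)]][row] <<- as.integer(allele)
    invisible()
  }
  set_hom <- function(row, allele) {
    if (is.na(allele) || allele <= 0) {
      drop_rows <<- c(drop_rows, row)
    } else {
      hemi <- g$a2[row] == W_PLACEHOLDER # preserve ZW hemizygous coding
      g$a1[row] <<- as.integer(allele)
      g$a2[row] <<- if (hemi) W_PLACEHOLDER else as.integer(allele)
      g$a3[row] <<- NA_integer_
      g$a4[row] <<- NA_integer_
    }
    invisible()
  }
  other_parent_allele <- function(par, marker, transmitted) {
    i <- match(paste(par, marker), gkey)
    if (is.na(i)) return(NA_integer_)
    slots <- c(g$a1[i], g$a2[i])
    if (slots[1] == transmitted) slots[2] else slots[1]
  }

  # ---- chromosomal abnormalities --------------------------------------
  kids <- ped$individual_id[ped$cohort %in% c("BC1", "BC2") &
                              ped$fate != "infertile_egg"]
  kids <- kids[kids %in% g$individual_id]
  if (length(kids) && sum(rates) > 0) {
    u <- stats::runif(length(kids))
    cum <- cumsum(rates)
    type_i <- findInterval(u, c(0, cum), left.open = TRUE)
    affected <- which(type_i >= 1 & type_i <= length(rates))
    mmix <- cfg$mechanism_mix / sum(cfg$mechanism_mix)
    for (a in affected) {
      kid <- kids[a]
      type <- names(rates)[type_i[a]]
      dam <- ped$dam_id[match(kid, ped$individual_id)]
      sire <- ped$sire_id[match(kid, ped$individual_id)]
      mech <- NA_character_
      side <- NA_character_
      chrom_lab <- "all"
      if (type %in% c("triploidy", "tetraploidy")) {
        mech <- sample(names(mmix), 1, prob = mmix)
        side <- if (mech == "polyspermy") "sire" else "dam"
        if (type == "tetraploidy") mech <- "MI+polyspermy"
        for (i in seq_len(nrow(auto_mk))) {
          m <- auto_mk$marker_id[i]
          row <- match(paste(kid, m), gkey)
          if (is.na(row)) next
          if (mech %in% c("MI", "MI+polyspermy")) {
            t_al <- trans_allele(kid, dam, auto_mk$chromosome[i],
                                 auto_mk$position_class[i])
            add_allele(row, other_parent_allele(dam, m, t_al))
          }
          if (mech %in% c("polyspermy", "MI+polyspermy")) {
            ps <- match(paste(sire, m), gkey)
            if (!is.na(ps)) add_allele(row, sample(c(g$a1[ps], g$a2[ps]), 1))
          }
          # MII: a duplicated chromatid adds no new allele length
        }
      } else if (type == "trisomy") {
        chrom_lab <- sample(unique(auto_mk$chromosome), 1)
        side <- sample(c("dam", "sire"), 1)
        mech <- sample(c("MI", "MII"), 1,
                       prob = mmix[c("MI", "MII")] / sum(mmix[c("MI", "MII")]))
        par <- if (side == "dam") dam else sire
        if (mech == "MI") {
          rows_mk <- auto_mk[auto_mk$chromosome == chrom_lab, , drop = FALSE]
          for (i in seq_len(nrow(rows_mk))) {
            m <- rows_mk$marker_id[i]
            row <- match(paste(kid, m), gkey)
            if (is.na(row)) next
            t_al <- trans_allele(kid, par, chrom_lab, rows_mk$position_class[i])
            add_allele(row, other_parent_allele(par, m, t_al))
          }
        }
      } else if (type == "haploidy") {
        side <- sample(c("dam", "sire"), 1)
        par <- if (side == "dam") dam else sire
        for (i in seq_len(nrow(mk))) {
          m <- mk$marker_id[i]
          row <- match(paste(kid, m), gkey)
          if (is.na(row)) next
          set_hom(row, trans_allele(kid, par, mk$chromosome[i],
                                    mk$position_class[i]))
        }
        mech <- "unknown"
      } else if (type == "monosomy") {
        chrom_lab <- sample(unique(auto_mk$chromosome), 1)
        side <- sample(c("dam", "sire"), 1) # the parent whose gamete lacked it
        keeper <- if (side == "dam") sire else dam
        rows_mk <- auto_mk[auto_mk$chromosome == chrom_lab, , drop = FALSE]
        for (i in seq_len(nrow(rows_mk))) {
          row <- match(paste(kid, rows_mk$marker_id[i]), gkey)
          if (is.na(row)) next
          set_hom(row, trans_allele(kid, keeper, chrom_lab,
                                    rows_mk$position_class[i]))
        }
        mech <- sample(c("MI", "MII"), 1)
      }
      events[[length(events) + 1L]] <- data.frame(
        individual_id = kid, marker_id = NA_character_,
        chromosome = chrom_lab, event = type,
        detail = paste(mech, side, sep = ";"), stringsAsFactors = FALSE)
    }
  }

  # ---- null alleles (allelic dropout) ---------------------------------
  if (cfg$null_allele_rate > 0) {
    eligible <- which(is.na(g$a3))
    hit <- eligible[stats::runif(length(eligible)) < cfg$null_allele_rate]
    for (row in hit) {
      a1 <- g$a1[row]; a2 <- g$a2[row]
      if (a1 > 0L && a2 > 0L && a1 != a2) {
        masked <- if (stats::runif(1) < 0.5) 1L else 2L
        kept <- if (masked == 1L) a2 else a1
        dropped <- if (masked == 1L) a1 else a2
        g$a1[row] <- kept; g$a2[row] <- kept
      } else if (a1 > 0L && a2 == W_PLACEHOLDER) {
        dropped <- a1
        drop_rows <- c(drop_rows, row)
      } else {
        next # apparent homozygote: dropout has no visible effect
      }
      events[[length(events) + 1L]] <- data.frame(
        individual_id = g$individual_id[row], marker_id = g$marker_id[row],
        chromosome = mk$chromosome[match(g$marker_id[row], mk$marker_id)],
        event = "null_mask", detail = as.character(dropped),
        stringsAsFactors = FALSE)
    }
  }

  if (length(drop_rows)) g <- g[-unique(drop_rows), , drop = FALSE]
  ds$genotypes <- g
  if (length(events)) {
    truth$events <- rbind(truth$events, do.call(rbind, events))
  }
  structure(list(dataset = ds, truth = truth, config = cfg),
            class = "cross_sim")
}

#' Reconcile deduced transmissions with the simulator truth log
#'
#' Joins each deduced transmission record to the truth log and compares the
#' deduced origin (1 = AUS) with the true origin of the transmitted allele.
#' On nuisance-free runs every deduced record must agree with the truth.
#'
#' @param records Records from [count_transmissions()].
#' @param truth A `truth_log`.
#' @param markers Marker map (for marker -> chromosome/class).
#' @return `records` with columns `truth_origin` and `agree` appended.
#' @export
reconcile_truth <- function(records, truth, markers) {
  tm <- truth$meioses
  tkey <- paste(tm$offspring_id, tm$parent_id, tm$chromosome)
  chrom <- markers$chromosome[match(records$marker_id, markers$marker_id)]
  class <- markers$position_class[match(records$marker_id, markers$marker_id)]
  i <- match(paste(records$offspring_id, records$parent_id, chrom), tkey)
  records$truth_origin <- ifelse(class == "centromeric",
                                 tm$cen_origin[i], tm$dist_origin[i])
  records$agree <- records$transmitted == records$truth_origin
  records
}
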