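# Allele-origin registry, null-allele inference, parental-pair classification,
# transmission deduction and counting. This is the core of the transmission
# ratio distortion analysis: every statistic downstream consumes the
# TransmissionRecord table produced here.

HYBRID_COHORTS <- c("F1", "BC1")

#' Build the allele-origin registry from founder genotypes
#'
#' Classifies every observed (marker, allele length) as of Australian
#' (`AUS`) or Timor (`TIM`) origin according to which founder pool it was
#' observed in. Alleles seen in both pools are `AMBIG`; alleles observed in
#' descendants but absent from all founders are registered as `AMBIG` with a
#' warning (possible mutation or uncorrected dropout).
#'
#' @param ds A validated `drive_dataset` containing founder genotypes
#'   (cohorts `FOUNDER_AUS` and `FOUNDER_TIM`).
#' @return A data frame of class `origin_registry` with columns `marker_id`,
#'   `allele`, `origin`.
#' @export
build_origin_registry <- function(ds) {
  ped <- ds$individuals
  g <- ds$genotypes
  co <- ped$cohort[match(g$individual_id, ped$individual_id)]
  long <- function(rows) {
    al <- c(rows$a1, rows$a2, rows$a3, rows$a4)
    mk <- rep(rows$marker_id, 4L)
    keep <- !is.na(al) & al > 0L
    unique(data.frame(marker_id = mk[keep], allele = al[keep],
                      stringsAsFactors = FALSE))
  }
  aus <- long(g[co == "FOUNDER_AUS", , drop = FALSE])
  tim <- long(g[co == "FOUNDER_TIM", , drop = FALSE])
  no_founder <- setdiff(unique(ds$markers$marker_id),
                        unique(c(aus$marker_id, tim$marker_id)))
  if (length(no_founder)) {
    stop_fmt("registry error: no founder genotypes for marker(s): %s",
             paste(no_founder, collapse = ", "))
  }
  aus$key <- paste(aus$marker_id, aus$allele)
  tim$key <- paste(tim$marker_id, tim$allele)
  shared <- intersect(aus$key, tim$key)
  reg <- rbind(
    data.frame(aus[, c("marker_id", "allele")],
               origin = ifelse(aus$key %in% shared, "AMBIG", "AUS"),
               stringsAsFactors = FALSE),
    data.frame(tim[!tim$key %in% shared, c("marker_id", "allele")],
               origin = "TIM", stringsAsFactors = FALSE)
  )
  # descendant alleles never seen in a founder
  desc <- long(g[!co %in% c("FOUNDER_AUS", "FOUNDER_TIM"), , drop = FALSE])
  desc$key <- paste(desc$marker_id, desc$allele)
  orphan <- desc[!desc$key %in% paste(reg$marker_id, reg$allele), , drop = FALSE]
  if (nrow(orphan)) {
    warn_fmt("%d allele(s) observed only in descendants; registered as AMBIG",
             nrow(orphan))
    reg <- rbind(reg, data.frame(orphan[, c("marker_id", "allele")],
                                 origin = "AMBIG", stringsAsFactors = FALSE))
  }
  reg <- reg[order(reg$marker_id, reg$allele), ]
  rownames(reg) <- NULL
  class(reg) <- c("origin_registry", "data.frame")
  reg
}

# Fast lookup environment: "marker allele" -> origin
origin_env <- function(registry) {
  e <- new.env(parent = emptyenv(), size = nrow(registry) * 2L)
  keys <- paste(registry$marker_id, registry$allele)
  for (i in seq_along(keys)) assign(keys[i], registry$origin[i], envir = e)
  e
}

origin_of <- function(oenv, marker_id, allele) {
  if (allele <= 0L) return("UNK")
  get0(paste(marker_id, allele), envir = oenv, ifnotfound = "UNK")
}

#' Infer null alleles (allelic dropouts) from pedigree inconsistencies
#'
#' An apparent homozygote whose genotype is Mendelian-inconsistent within some
#' genotyped trio (as offspring or as parent), but becomes consistent when one
#' allele slot is rewritten to the NULL placeholder, has that slot rewritten.
#' Inference is conservative: a genotype is rewritten only when it is the
#' unique candidate that restores consistency of the violating trio, so calls
#' have precision 1 against simulated truth (recall below 1 is expected).
#' Unresolvable inconsistencies are left untouched and surface through
#' [check_mendelian_consistency()].
#'
#' @param ds A validated `drive_dataset`.
#' @param exclude_individuals Offspring ids to skip (e.g. carriers of
#'   chromosomal abnormalities flagged by [detect_anomalies()]).
#' @param max_passes Maximum inference sweeps (rewrites can cascade).
#' @return A list with `dataset` (genotypes updated in place) and `calls`
#'   (data frame `individual_id`, `marker_id`, `kept_allele`).
#' @export
infer_null_alleles <- function(ds, exclude_individuals = character(),
                               max_passes = 4L) {
  g <- ds$genotypes
  gkey <- paste(g$individual_id, g$marker_id)
  calls <- data.frame(individual_id = character(), marker_id = character(),
                      kept_allele = integer(), stringsAsFactors = FALSE)
  for (pass in seq_len(max_passes)) {
    ds$genotypes <- g
    tt <- build_trio_table(ds)
    if (is.null(tt) || nrow(tt) == 0L) break
    tt <- tt[!tt$individual_id %in% exclude_individuals & is.na(tt$o3), ,
             drop = FALSE]
    if (nrow(tt) == 0L) break
    cons <- trio_consistent(tt$o1, tt$o2, tt$d1, tt$d2, tt$s1, tt$s2,
                            tt$z_female_dam, tt$sex)
    viol <- which(!cons)
    if (!length(viol)) break
    rewrites <- character()
    for (v in viol) {
      row <- tt[v, ]
      cand <- list()
      if (row$o1 == row$o2 && row$o1 > 0L) {
        cand <- c(cand, list(c(row$individual_id, "off")))
      }
      if (row$d1 == row$d2 && row$d1 > 0L) {
        cand <- c(cand, list(c(row$dam_id, "dam")))
      }
      if (row$s1 == row$s2 && row$s1 > 0L) {
        cand <- c(cand, list(c(row$sire_id, "sire")))
      }
      fixers <- character()
      for (cd in cand) {
        o1 <- row$o1; o2 <- row$o2; d1 <- row$d1; d2 <- row$d2
        s1 <- row$s1; s2 <- row$s2
        switch(cd[2],
               off = { o2 <- NULL_ALLELE },
               dam = { d2 <- NULL_ALLELE },
               sire = { s2 <- NULL_ALLELE })
        if (trio_consistent(o1, o2, d1, d2, s1, s2,
                            row$z_female_dam, row$sex)) {
          fixers <- c(fixers, cd[1])
        }
      }
      if (length(fixers) == 1L) {
        rewrites <- c(rewrites, paste(fixers, row$marker_id))
      }
    }
    rewrites <- unique(rewrites)
    if (!length(rewrites)) break
    idx <- match(rewrites, gkey)
    idx <- idx[!is.na(idx)]
    # guard: only rewrite still-apparent homozygotes
    idx <- idx[g$a1[idx] == g$a2[idx] & g$a1[idx] > 0L]
    if (!length(idx)) break
    calls <- rbind(calls, data.frame(individual_id = g$individual_id[idx],
                                     marker_id = g$marker_id[idx],
                                     kept_allele = g$a1[idx],
                                     stringsAsFactors = FALSE))
    g$a2[idx] <- NULL_ALLELE
  }
  ds$genotypes <- g
  list(dataset = ds, calls = calls)
}

# ---- pair classification and deduction -------------------------------------

# Deduce the focal transmission for one stored offspring genotype.
# Returns "1", "0", "ambiguous" or "excluded".
deduce_one <- function(o1, o2, d_slots, s_slots, focal, marker_id, oenv,
                       z_female_dam = FALSE, off_sex = NA_character_) {
  origins <- character(0)
  for (gd in d_slots) {
    if (z_female_dam) {
      if (gd == W_PLACEHOLDER && !is.na(off_sex) && off_sex == "M") next
      if (gd != W_PLACEHOLDER && !is.na(off_sex) && off_sex == "F") next
    }
    for (gs in s_slots) {
      ok <- (slot_match(o1, gd) && slot_match(o2, gs)) ||
        (slot_match(o2, gd) && slot_match(o1, gs))
      if (!ok) next
      gf <- if (focal == "dam") gd else gs
      origins <- c(origins, origin_of(oenv, marker_id, gf))
    }
  }
  if (!length(origins)) return("excluded")
  u <- unique(origins)
  if (length(u) == 1L && u == "AUS") return("1")
  if (length(u) == 1L && u == "TIM") return("0")
  "ambiguous"
}

# Enumerate the stored genotype forms (signature + sex context) a pair can
# produce, as a data frame with columns o1, o2, sex.
producible_forms <- function(d_slots, s_slots, z_female_dam) {
  forms <- list()
  for (gd in d_slots) {
    for (gs in s_slots) {
      pos <- c(gd, gs)
      pos <- pos[pos > 0L]
      sex <- NA_character_
      if (z_female_dam) sex <- if (gd == W_PLACEHOLDER) "F" else "M"
      if (length(pos) == 2L) {
        pos <- sort(pos)
        forms[[length(forms) + 1L]] <- c(pos[1], pos[2], sex)
      } else if (length(pos) == 1L) {
        if (z_female_dam && gd == W_PLACEHOLDER) {
          # hemizygous daughter: stored with explicit W slot
          forms[[length(forms) + 1L]] <- c(pos, W_PLACEHOLDER, sex)
        } else {
          # single observable peak: stored as apparent homozygote when that is
          # trio-consistent, otherwise the inferred-null form
          hom_ok <- trio_consistent(pos, pos, d_slots[1], d_slots[2],
                                    s_slots[1], s_slots[2], z_female_dam, sex)
          if (hom_ok) {
            forms[[length(forms) + 1L]] <- c(pos, pos, sex)
          } else {
            forms[[length(forms) + 1L]] <- c(pos, NULL_ALLELE, sex)
          }
        }
      }
      # no observable allele: egg yields no genotype record; nothing to count
    }
  }
  if (!length(forms)) {
    return(data.frame(o1 = integer(), o2 = integer(), sex = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, forms)
  out <- data.frame(o1 = as.integer(m[, 1]), o2 = as.integer(m[, 2]),
                    sex = m[, 3], stringsAsFactors = FALSE)
  unique(out)
}

# Focal eligibility of one parent's slots: "eligible" (AUS/TIM heterozygote),
# "null_het" (heterozygous with an inferred null: excluded from counting) or
# "not_focal".
focal_status <- function(slots, marker_id, oenv) {
  if (all(slots > 0L)) {
    orx <- c(origin_of(oenv, marker_id, slots[1]),
             origin_of(oenv, marker_id, slots[2]))
    if (setequal(orx, c("AUS", "TIM")) && slots[1] != slots[2]) {
      return("eligible")
    }
    return("not_focal")
  }
  if (sum(slots > 0L) == 1L && any(slots == NULL_ALLELE)) {
    a <- slots[slots > 0L]
    if (origin_of(oenv, marker_id, a) %in% c("AUS", "TIM")) return("null_het")
  }
  "not_focal"
}

#' Classify a parental pair's informativeness at a marker
#'
#' Enumerates every offspring genotype the pair can produce (including
#' single-peak forms arising from null alleles and the maternal W at Z-linked
#' markers) and checks whether each uniquely determines the origin
#' (Australian vs Timor) of the focal parent's transmitted allele. A pair is
#' `fully_informative` when every producible genotype is deducible,
#' `partial_ABxAB` when both parents carry exactly the same two allele
#' lengths (only homozygous offspring are then deducible), and
#' `uninformative` otherwise. The focal parent must be heterozygous for one
#' Australian and one Timor allele; a focal parent heterozygous with an
#' inferred null is uninformative. At Z-linked markers a ZW female is
#' hemizygous and never focal, so Z-linked transmission is effectively tested
#' in males only. When both parents are AUS/TIM heterozygotes, one
#' classification per focal parent is returned.
#'
#' @param dam_genotype,sire_genotype Integer vectors of length 2 (allele
#'   slots; 0 = inferred null, -1 = W placeholder).
#' @param registry An `origin_registry` (or the environment from it).
#' @param marker_id Marker identifier (used for origin lookup).
#' @param z_female_dam `TRUE` when the marker is Z-linked and the dam is a ZW
#'   female.
#' @param dam_id,sire_id Parent identifiers carried into the result.
#' @return A data frame with one row per focal candidate: `dam_id`,
#'   `sire_id`, `marker_id`, `focal` (`"dam"`/`"sire"`/`NA`),
#'   `focal_parent`, `status`.
#' @export
classify_pair <- function(dam_genotype, sire_genotype, registry, marker_id,
                          z_female_dam = FALSE,
                          dam_id = "dam", sire_id = "sire") {
  oenv <- if (is.environment(registry)) registry else origin_env(registry)
  d <- as.integer(dam_genotype[1:2])
  s <- as.integer(sire_genotype[1:2])
  res <- list()
  for (side in c("dam", "sire")) {
    slots <- if (side == "dam") d else s
    fs <- focal_status(slots, marker_id, oenv)
    if (fs == "not_focal") next
    if (fs == "null_het") {
      status <- "uninformative"
    } else {
      forms <- producible_forms(d, s, z_female_dam)
      results <- vapply(seq_len(nrow(forms)), function(i) {
        deduce_one(forms$o1[i], forms$o2[i], d, s, side, marker_id, oenv,
                   z_female_dam, forms$sex[i])
      }, character(1))
      if (all(results %in% c("0", "1"))) {
        status <- "fully_informative"
      } else if (setequal(d[d > 0L], s[s > 0L]) &&
                 length(unique(d[d > 0L])) == 2L &&
                 all(d > 0L) && all(s > 0L)) {
        status <- "partial_ABxAB"
      } else {
        status <- "uninformative"
      }
    }
    res[[length(res) + 1L]] <- data.frame(
      dam_id = dam_id, sire_id = sire_id, marker_id = marker_id,
      focal = side, focal_parent = if (side == "dam") dam_id else sire_id,
      status = status, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(dam_id = dam_id, sire_id = sire_id,
                      marker_id = marker_id, focal = NA_character_,
                      focal_parent = NA_character_, status = "uninformative",
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Deduce one transmission from a classified pair and an offspring genotype
#'
#' Applies the deduction engine of [classify_pair()] to a single offspring:
#' for `fully_informative` pairs every Mendelian-consistent genotype yields 1
#' (Australian allele transmitted) or 0 (Timor); for `partial_ABxAB` pairs
#' homozygous offspring are deducible and heterozygous offspring are
#' `"ambiguous"`; `uninformative` pairs and Mendelian-inconsistent or missing
#' offspring genotypes yield `"excluded"`.
#'
#' @param dam_genotype,sire_genotype,registry,marker_id,z_female_dam As in
#'   [classify_pair()].
#' @param focal `"dam"` or `"sire"`: which parent's transmission to deduce.
#' @param offspring_genotype Integer vector of length 2, or `NULL` for a
#'   missing genotype (infertile or lost egg).
#' @param offspring_sex `"F"`, `"M"` or `NA`; used only at Z-linked markers.
#' @param status Pair status from [classify_pair()]; if omitted it is
#'   recomputed.
#' @return `"1"`, `"0"`, `"ambiguous"` or `"excluded"`.
#' @export
deduce_transmission <- function(dam_genotype, sire_genotype, focal,
                                offspring_genotype, registry, marker_id,
                                z_female_dam = FALSE,
                                offspring_sex = NA_character_,
                                status = NULL) {
  oenv <- if (is.environment(registry)) registry else origin_env(registry)
  if (is.null(status)) {
    cls <- classify_pair(dam_genotype, sire_genotype, oenv, marker_id,
                         z_female_dam)
    row <- cls[!is.na(cls$focal) & cls$focal == focal, , drop = FALSE]
    status <- if (nrow(row)) row$status[1] else "uninformative"
  }
  if (status == "uninformative") return("excluded")
  if (is.null(offspring_genotype) || anyNA(offspring_genotype[1:2])) {
    return("excluded")
  }
  deduce_one(as.integer(offspring_genotype[1]),
             as.integer(offspring_genotype[2]),
             as.integer(dam_genotype[1:2]), as.integer(sire_genotype[1:2]),
             focal, marker_id, oenv, z_female_dam, offspring_sex)
}

#' Build the informativeness ledger
#'
#' Small constructor for the accounting object reported alongside
#' transmission counts: total deducible opportunities, informative count,
#' percentage and exclusion reasons.
#'
#' @param total Total allele-transmission opportunities (offspring x marker x
#'   hybrid-parent combinations with an offspring genotype present).
#' @param informative Number of informative (deduced) transmissions.
#' @param exclusions Named list/vector of exclusion counts by reason.
#' @param missing_genotype Opportunities with no offspring genotype record.
#' @return A list of class `informativeness_ledger` with fields
#'   `total_transmissions`, `informative`, `informative_pct` (percentage,
#'   rounded to 0.1), `exclusions`, `missing_genotype`.
#' @export
informativeness_ledger <- function(total, informative, exclusions = list(),
                                   missing_genotype = 0L) {
  stopifnot(informative <= total)
  structure(list(
    total_transmissions = as.integer(total),
    informative = as.integer(informative),
    informative_pct = round(100 * informative / total, 1),
    exclusions = as.list(exclusions),
    missing_genotype = as.integer(missing_genotype)
  ), class = "informativeness_ledger")
}

# ---- fast scalar deduction path used by count_transmissions ----------------
# Origin codes: 1 = AUS, 0 = TIM, -1 = AMBIG/unknown.

sm_scalar <- function(s, g) {
  if (s == 0L) TRUE
  else if (s == -1L) g == -1L
  else g == s || g == 0L || g == -1L
}

# any one-allele-per-parent assignment consistent with stored (o1, o2)?
consistent_scalar <- function(o1, o2, d1, d2, s1, s2, zfd, sex) {
  for (gd in c(d1, d2)) {
    if (zfd && !is.na(sex)) {
      if (gd == -1L && sex == "M") next
      if (gd != -1L && sex == "F") next
    }
    for (gs in c(s1, s2)) {
      if ((sm_scalar(o1, gd) && sm_scalar(o2, gs)) ||
          (sm_scalar(o2, gd) && sm_scalar(o1, gs))) return(TRUE)
    }
  }
  FALSE
}

# deduce focal origin: 1/0 deduced, -1 ambiguous, -2 no consistent assignment
deduce_fast <- function(o1, o2, d1, d2, s1, s2, focal_dam, f1, f2,
                        or1, or2, zfd, sex) {
  saw <- -9L
  for (gd in c(d1, d2)) {
    if (zfd && !is.na(sex)) {
      if (gd == -1L && sex == "M") next
      if (gd != -1L && sex == "F") next
    }
    for (gs in c(s1, s2)) {
      ok <- (sm_scalar(o1, gd) && sm_scalar(o2, gs)) ||
        (sm_scalar(o2, gd) && sm_scalar(o1, gs))
      if (!ok) next
      gf <- if (focal_dam) gd else gs
      org <- if (gf == f1) or1 else if (gf == f2) or2 else -1L
      if (saw == -9L) saw <- org
      else if (saw != org) return(-1L)
      if (saw == -1L) return(-1L)
    }
  }
  if (saw == -9L) -2L else saw
}

# classify one focal side; assumes focal is an eligible AUS/TIM heterozygote.
# Returns "fully_informative", "partial_ABxAB" or "uninformative".
classify_fast <- function(d1, d2, s1, s2, focal_dam, f1, f2, or1, or2, zfd) {
  all_ok <- TRUE
  for (gd in c(d1, d2)) {
    for (gs in c(s1, s2)) {
      pos <- c(gd, gs)
      pos <- pos[pos > 0L]
      sex <- if (zfd) (if (gd == -1L) "F" else "M") else NA_character_
      if (length(pos) == 2L) {
        o1 <- min(pos); o2 <- max(pos)
      } else if (length(pos) == 1L) {
        if (zfd && gd == -1L) {
          o1 <- -1L; o2 <- pos
        } else if (consistent_scalar(pos, pos, d1, d2, s1, s2, zfd, sex)) {
          o1 <- pos; o2 <- pos
        } else {
          o1 <- 0L; o2 <- pos
        }
      } else next
      r <- deduce_fast(o1, o2, d1, d2, s1, s2, focal_dam, f1, f2, or1, or2,
                       zfd, sex)
      if (r < 0L) { all_ok <- FALSE; break }
    }
    if (!all_ok) break
  }
  if (all_ok) return("fully_informative")
  dp <- c(d1, d2); sp <- c(s1, s2)
  if (all(dp > 0L) && all(sp > 0L) && d1 != d2 &&
      setequal(dp, sp)) return("partial_ABxAB")
  "uninformative"
}

#' Count informative allele transmissions across the pedigree
#'
#' For every breeding pair, marker and focal hybrid parent (cohort F1 or
#' BC1), classifies the pair with [classify_pair()] and deduces each
#' offspring's transmitted allele origin. Offspring carrying a flagged
#' chromosomal abnormality are excluded for the affected chromosomes via
#' [apply_exclusions()] when `anomaly_calls` is supplied.
#'
#' @param ds A validated `drive_dataset` (after null inference).
#' @param registry An `origin_registry`; built from `ds` when `NULL`.
#' @param anomaly_calls Optional data frame from [detect_anomalies()].
#' @return A list with `records` (one row per deduced transmission:
#'   `parent_id`, `parent_sex`, `parent_cohort`, `offspring_id`, `marker_id`,
#'   `chromosome`, `position_class`, `transmitted` in {0,1}), `summary`
#'   (counts by marker x parent_sex x parent_cohort x position_class) and
#'   `ledger` (an `informativeness_ledger`).
#' @export
count_transmissions <- function(ds, registry = NULL, anomaly_calls = NULL) {
  if (is.null(registry)) registry <- build_origin_registry(ds)
  oenv <- origin_env(registry)
  ped <- ds$individuals
  g <- ds$genotypes
  mk <- ds$markers
  gkey <- paste(g$individual_id, g$marker_id)

  off <- ped[!is.na(ped$dam_id) & !is.na(ped$sire_id) &
               ped$cohort %in% c("F1", "BC1", "BC2"), , drop = FALSE]
  pair_key <- paste(off$dam_id, off$sire_id)
  pairs <- unique(data.frame(dam_id = off$dam_id, sire_id = off$sire_id,
                             stringsAsFactors = FALSE))
  kids_by_pair <- split(seq_len(nrow(off)), pair_key)
  cohort_of <- function(id) ped$cohort[match(id, ped$individual_id)]

  # record accumulators (column-wise, concatenated once at the end)
  acc <- list(parent_id = list(), parent_sex = list(), parent_cohort = list(),
              offspring_id = list(), marker_id = list(), chromosome = list(),
              position_class = list(), transmitted = list())
  nchunk <- 0L
  excl <- c(pair_uninformative = 0L, offspring_ambiguous = 0L,
            mendelian_inconsistent = 0L, non_diploid = 0L,
            parent_genotype_missing = 0L)
  missing_geno <- 0L

  orig_code <- function(marker, allele) {
    o <- origin_of(oenv, marker, allele)
    if (o == "AUS") 1L else if (o == "TIM") 0L else -1L
  }

  for (pi in seq_len(nrow(pairs))) {
    dam <- pairs$dam_id[pi]; sire <- pairs$sire_id[pi]
    krows <- kids_by_pair[[paste(dam, sire)]]
    kids <- off$individual_id[krows]
    kid_sex <- off$sex[krows]
    dam_hyb <- cohort_of(dam) %in% HYBRID_COHORTS
    sire_hyb <- cohort_of(sire) %in% HYBRID_COHORTS
    if (!dam_hyb && !sire_hyb) next
    ki_all <- match(paste(rep(kids, each = nrow(mk)), mk$marker_id), gkey)
    dim(ki_all) <- c(nrow(mk), length(kids))
    di_all <- match(paste(dam, mk$marker_id), gkey)
    si_all <- match(paste(sire, mk$marker_id), gkey)
    for (mi in seq_len(nrow(mk))) {
      marker <- mk$marker_id[mi]
      zfd <- mk$is_z_linked[mi]
      ki <- ki_all[mi, ]
      present <- !is.na(ki)
      n_sides <- dam_hyb + sire_hyb
      missing_geno <- missing_geno + sum(!present) * n_sides
      if (!any(present)) next
      n_kids <- sum(present)
      di <- di_all[mi]; si <- si_all[mi]
      if (is.na(di) || is.na(si)) {
        excl["parent_genotype_missing"] <-
          excl["parent_genotype_missing"] + n_kids * n_sides
        next
      }
      d1 <- g$a1[di]; d2 <- g$a2[di]
      s1 <- g$a1[si]; s2 <- g$a2[si]
      ko1 <- g$a2[ki[present]]; ko2 <- g$a1[ki[present]] # (min, max) order
      ko3 <- g$a3[ki[present]]
      ksex <- kid_sex[present]
      kid_ids <- kids[present]
      for (side in c("dam", "sire")[c(dam_hyb, sire_hyb)]) {
        focal_dam <- side == "dam"
        f1 <- if (focal_dam) d1 else s1
        f2 <- if (focal_dam) d2 else s2
        status <- "uninformative"
        or1 <- or2 <- -1L
        if (f1 > 0L && f2 > 0L && f1 != f2) {
          or1 <- orig_code(marker, f1)
          or2 <- orig_code(marker, f2)
          if ((or1 == 1L && or2 == 0L) || (or1 == 0L && or2 == 1L)) {
            status <- classify_fast(d1, d2, s1, s2, focal_dam, f1, f2,
                                    or1, or2, zfd)
          }
        }
        if (status == "uninformative") {
          excl["pair_uninformative"] <- excl["pair_uninformative"] + n_kids
          next
        }
        # deduce unique stored signatures once, then map to offspring
        sig <- paste(ko1, ko2,
                     if (zfd) ifelse(is.na(ksex), "U", ksex) else "")
        usig <- which(!duplicated(sig))
        res_u <- integer(length(usig))
        for (jj in seq_along(usig)) {
          j <- usig[jj]
          res_u[jj] <- if (!is.na(ko3[j])) -3L else
            deduce_fast(ko1[j], ko2[j], d1, d2, s1, s2, focal_dam, f1, f2,
                        or1, or2, zfd, ksex[j])
        }
        res <- res_u[match(sig, sig[usig])]
        excl["offspring_ambiguous"] <-
          excl["offspring_ambiguous"] + sum(res == -1L)
        excl["mendelian_inconsistent"] <-
          excl["mendelian_inconsistent"] + sum(res == -2L)
        excl["non_diploid"] <- excl["non_diploid"] + sum(res == -3L)
        hit <- res >= 0L
        if (any(hit)) {
          nchunk <- nchunk + 1L
          nh <- sum(hit)
          acc$parent_id[[nchunk]] <- rep(if (focal_dam) dam else sire, nh)
          acc$parent_sex[[nchunk]] <- rep(if (focal_dam) "F" else "M", nh)
          acc$parent_cohort[[nchunk]] <-
            rep(cohort_of(if (focal_dam) dam else sire), nh)
          acc$offspring_id[[nchunk]] <- kid_ids[hit]
          acc$marker_id[[nchunk]] <- rep(marker, nh)
          acc$chromosome[[nchunk]] <- rep(mk$chromosome[mi], nh)
          acc$position_class[[nchunk]] <- rep(mk$position_class[mi], nh)
          acc$transmitted[[nchunk]] <- res[hit]
        }
      }
    }
  }
  records <- if (nchunk) {
    data.frame(parent_id = unlist(acc$parent_id),
               parent_sex = unlist(acc$parent_sex),
               parent_cohort = unlist(acc$parent_cohort),
               offspring_id = unlist(acc$offspring_id),
               marker_id = unlist(acc$marker_id),
               chromosome = unlist(acc$chromosome),
               position_class = unlist(acc$position_class),
               transmitted = as.integer(unlist(acc$transmitted)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(parent_id = character(), parent_sex = character(),
               parent_cohort = character(), offspring_id = character(),
               marker_id = character(), chromosome = character(),
               position_class = character(), transmitted = integer(),
               stringsAsFactors = FALSE)
  }
  dropped <- 0L
  if (!is.null(anomaly_calls) && nrow(anomaly_calls) &&
      nrow(records)) {
    hybrids <- ped$individual_id[ped$cohort %in% HYBRID_COHORTS]
    before <- nrow(records)
    records <- apply_exclusions(records, anomaly_calls, hybrids, ds)
    dropped <- before - nrow(records)
  }
  total <- nrow(records) + sum(excl) + dropped
  ledger <- informativeness_ledger(
    total = total, informative = nrow(records),
    exclusions = c(as.list(excl), list(anomaly_excluded = dropped)),
    missing_genotype = missing_geno)
  list(records = records, summary = summarize_transmissions(records),
       ledger = ledger)
}

#' Summarize transmission records
#'
#' Aggregates counts of Australian (successes) and Timor (failures)
#' transmissions by marker, parent sex, parent cohort and position class.
#' Marginals are additive: pooled counts are sums of per-marker counts.
#'
#' @param records The `records` table from [count_transmissions()].
#' @return Data frame with `marker_id`, `chromosome`, `position_class`,
#'   `parent_sex`, `parent_cohort`, `n`, `successes`.
#' @export
summarize_transmissions <- function(records) {
  if (!nrow(records)) {
    return(data.frame(marker_id = character(), chromosome = character(),
                      position_class = character(), parent_sex = character(),
                      parent_cohort = character(), n = integer(),
                      successes = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    cbind(n = rep(1L, nrow(records)), successes = records$transmitted),
    by = list(marker_id = records$marker_id,
              chromosome = records$chromosome,
              position_class = records$position_class,
              parent_sex = records$parent_sex,
              parent_cohort = records$parent_cohort),
    FUN = sum)
  agg[order(agg$marker_id, agg$parent_sex, agg$parent_cohort), ]
}

#' Restrict transmission records to robustness subsets
#'
#' `heterozygous_parents` keeps records from pairs in which both parents are
#' heterozygous for two observable alleles with no inferred null at the
#' marker (the subset that rules out undetected null alleles).
#' `no_inbreeding` keeps records from pairs that cannot produce offspring
#' homozygous for any Australian allele (the subset that rules out
#' inbreeding depression against Australian haplotypes).
#'
#' @param records Records from [count_transmissions()].
#' @param ds The dataset the records came from.
#' @param which `"heterozygous_parents"` or `"no_inbreeding"`.
#' @param registry Optional `origin_registry` (rebuilt from `ds` if `NULL`).
#' @return The filtered records.
#' @export
subset_transmissions <- function(records, ds,
                                 which = c("heterozygous_parents",
                                           "no_inbreeding"),
                                 registry = NULL) {
  which <- match.arg(which)
  if (!nrow(records)) return(records)
  if (is.null(registry)) registry <- build_origin_registry(ds)
  oenv <- origin_env(registry)
  ped <- ds$individuals
  g <- ds$genotypes
  gkey <- paste(g$individual_id, g$marker_id)
  dam <- ped$dam_id[match(records$offspring_id, ped$individual_id)]
  sire <- ped$sire_id[match(records$offspring_id, ped$individual_id)]
  di <- match(paste(dam, records$marker_id), gkey)
  si <- match(paste(sire, records$marker_id), gkey)
  d1 <- g$a1[di]; d2 <- g$a2[di]; s1 <- g$a1[si]; s2 <- g$a2[si]
  if (which == "heterozygous_parents") {
    keep <- d1 > 0L & d2 > 0L & d1 != d2 & s1 > 0L & s2 > 0L & s1 != s2
  } else {
    # shared Australian allele between the parents => an AUS homozygote is
    # producible => possible inbreeding depression; drop the pair
    keep <- rep(TRUE, nrow(records))
    key <- paste(dam, sire, records$marker_id)
    for (uk in unique(key)) {
      i <- match(uk, key)
      shared <- intersect(c(d1[i], d2[i]), c(s1[i], s2[i]))
      shared <- shared[shared > 0L]
      if (length(shared)) {
        orx <- vapply(shared, function(a)
          origin_of(oenv, records$marker_id[i], a), character(1))
        if (any(orx == "AUS")) keep[key == uk] <- FALSE
      }
    }
  }
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}
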