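# Trio-level Mendelian consistency machinery shared by the dataset checker,
# null-allele inference and the transmission-deduction engine.
#
# Matching semantics (post-inference genotypes taken at face value):
#   * an offspring slot equal to NULL_ALLELE (0) is a wildcard for a dropped
#     allele and matches any parental gamete;
#   * an offspring slot equal to W_PLACEHOLDER (-1) matches only a maternal W
#     gamete;
#   * a positive offspring slot matches a gamete of the same length, or a
#     parental NULL gamete (the transmitted allele failed to amplify in the
#     parent as well), or a maternal W gamete (the second observable slot is
#     then a duplicate peak of a hemizygous genotype);
#   * at a Z-linked marker a maternal W gamete implies a female offspring and
#     a maternal Z gamete implies a male offspring (daughters receive Z from
#     their sire).

# Vectorised slot match: can stored offspring slot `s` have come from gamete `g`?
slot_match <- function(s, g) {
  (s == NULL_ALLELE) |
    (s == W_PLACEHOLDER & g == W_PLACEHOLDER) |
    (s > 0L & (g == s | g == NULL_ALLELE | g == W_PLACEHOLDER))
}

# Vectorised: is offspring (o1, o2) consistent with some one-allele-per-parent
# assignment from dam slots (d1, d2) and sire slots (s1, s2)?
# `z_female_dam` flags rows where the marker is Z-linked and the dam is ZW (so
# her gametes are sex-determining); `off_sex` is "F", "M" or NA.
trio_consistent <- function(o1, o2, d1, d2, s1, s2,
                            z_female_dam = FALSE, off_sex = NA_character_) {
  n <- length(o1)
  z_female_dam <- rep_len(z_female_dam, n)
  off_sex <- rep_len(off_sex, n)
  any_ok <- rep(FALSE, n)
  for (gd in list(d1, d2)) {
    sex_ok <- !z_female_dam |
      ifelse(gd == W_PLACEHOLDER,
             is.na(off_sex) | off_sex != "M",
             is.na(off_sex) | off_sex != "F")
    for (gs in list(s1, s2)) {
      ok <- (slot_match(o1, gd) & slot_match(o2, gs)) |
        (slot_match(o2, gd) & slot_match(o1, gs))
      any_ok <- any_ok | (ok & sex_ok)
    }
  }
  any_ok
}

# Build the trio genotype table used by the checker and null inference:
# one row per (offspring, marker) where the offspring and both parents have a
# genotype record. Columns carry ids, slots and Z/sex context.
build_trio_table <- function(ds) {
  ped <- ds$individuals
  g <- ds$genotypes
  off <- ped[!is.na(ped$dam_id) & !is.na(ped$sire_id),
             c("individual_id", "sex", "dam_id", "sire_id")]
  if (nrow(off) == 0L) {
    return(NULL)
  }
  gg <- g[, c("individual_id", "marker_id", "a1", "a2", "a3", "a4")]
  t1 <- merge(off, gg, by = "individual_id")
  names(t1)[names(t1) %in% c("a1", "a2", "a3", "a4")] <- c("o1", "o2", "o3", "o4")
  gd <- gg[, c("individual_id", "marker_id", "a1", "a2")]
  names(gd) <- c("dam_id", "marker_id", "d1", "d2")
  t2 <- merge(t1, gd, by = c("dam_id", "marker_id"))
  gs <- gg[, c("individual_id", "marker_id", "a1", "a2")]
  names(gs) <- c("sire_id", "marker_id", "s1", "s2")
  t3 <- merge(t2, gs, by = c("sire_id", "marker_id"))
  zmap <- ds$markers$is_z_linked[match(t3$marker_id, ds$markers$marker_id)]
  dam_sex <- ped$sex[match(t3$dam_id, ped$individual_id)]
  t3$z_female_dam <- zmap & !is.na(dam_sex) & dam_sex == "F"
  t3
}

#' Check Mendelian consistency of all genotyped trios
#'
#' For every offspring with both parents genotyped at a marker, checks whether
#' some assignment of one allele from each parent (allowing inferred null
#' alleles and the maternal W placeholder at Z-linked markers) explains the
#' offspring genotype. Offspring genotypes with more than two alleles at a
#' marker are not diploid-testable and are flagged for the anomaly screen
#' instead.
#'
#' @param ds A validated dataset (see [read_dataset()]).
#' @return A data frame of violation records with columns `individual_id`,
#'   `marker_id` and `reason` (`"no_parental_assignment"` or
#'   `"non_diploid_defer_anomaly"`). Zero rows when all trios are consistent.
#' @export
check_mendelian_consistency <- function(ds) {
  tt <- build_trio_table(ds)
  empty <- data.frame(individual_id = character(), marker_id = character(),
                      reason = character(), stringsAsFactors = FALSE)
  if (is.null(tt) || nrow(tt) == 0L) {
    return(empty)
  }
  multi <- !is.na(tt$o3)
  cons <- trio_consistent(tt$o1, tt$o2, tt$d1, tt$d2, tt$s1, tt$s2,
                          tt$z_female_dam, tt$sex)
  out <- rbind(
    data.frame(individual_id = tt$individual_id[multi],
               marker_id = tt$marker_id[multi],
               reason = rep("non_diploid_defer_anomaly", sum(multi)),
               stringsAsFactors = FALSE),
    data.frame(individual_id = tt$individual_id[!multi & !cons],
               marker_id = tt$marker_id[!multi & !cons],
               reason = rep("no_parental_assignment", sum(!multi & !cons)),
               stringsAsFactors = FALSE)
  )
  out[order(out$individual_id, out$marker_id), , drop = FALSE]
}
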