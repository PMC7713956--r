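# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately re-derive behaviour with naive nested loops and
# their own conventions, independent of the package's vectorised engines.

# ---- brute-force trio / deduction oracle -----------------------------------
# Conventions (mirrors the data model, derived independently): stored slot 0
# is a wildcard for a dropped allele; -1 is the maternal W and matches only a
# W gamete; a positive slot matches the same length, a parental null gamete,
# or a maternal W gamete. At a Z-linked marker a W gamete implies a female
# offspring, a maternal Z gamete a male offspring.

oracle_slot_ok <- function(s, g) {
  if (s == 0) return(TRUE)
  if (s == -1) return(g == -1)
  (g == s) || (g == 0) || (g == -1)
}

oracle_assignments <- function(off, dam, sire, zfd = FALSE, sex = NA) {
  found <- list()
  for (i in 1:2) {
    for (j in 1:2) {
      gd <- dam[i]; gs <- sire[j]
      if (zfd && !is.na(sex)) {
        if (gd == -1 && sex == "M") next
        if (gd != -1 && sex == "F") next
      }
      direct <- oracle_slot_ok(off[1], gd) && oracle_slot_ok(off[2], gs)
      crossed <- oracle_slot_ok(off[2], gd) && oracle_slot_ok(off[1], gs)
      if (direct || crossed) found[[length(found) + 1]] <- c(gd, gs)
    }
  }
  found
}

oracle_consistent <- function(off, dam, sire, zfd = FALSE, sex = NA) {
  length(oracle_assignments(off, dam, sire, zfd, sex)) > 0
}

# deduce the focal parent's transmitted origin for one offspring genotype
oracle_deduce <- function(off, dam, sire, focal, origin_map, zfd = FALSE,
                          sex = NA) {
  asn <- oracle_assignments(off, dam, sire, zfd, sex)
  if (!length(asn)) return("excluded")
  orgs <- unique(vapply(asn, function(a) {
    gf <- if (focal == "dam") a[1] else a[2]
    if (gf <= 0) "UNK" else origin_map[[as.character(gf)]] %||% "UNK"
  }, character(1)))
  if (identical(orgs, "AUS")) return("1")
  if (identical(orgs, "TIM")) return("0")
  "ambiguous"
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# every stored genotype form the pair can produce, with its sex context
oracle_forms <- function(dam, sire, zfd = FALSE) {
  forms <- list()
  for (i in 1:2) {
    for (j in 1:2) {
      gd <- dam[i]; gs <- sire[j]
      pos <- c(gd, gs)
      pos <- pos[pos > 0]
      sex <- if (zfd) (if (gd == -1) "F" else "M") else NA
      if (length(pos) == 2) {
        forms[[length(forms) + 1]] <- list(off = sort(pos), sex = sex)
      } else if (length(pos) == 1) {
        if (zfd && gd == -1) {
          forms[[length(forms) + 1]] <- list(off = c(pos, -1), sex = sex)
        } else if (oracle_consistent(c(pos, pos), dam, sire, zfd, sex)) {
          forms[[length(forms) + 1]] <- list(off = c(pos, pos), sex = sex)
        } else {
          forms[[length(forms) + 1]] <- list(off = c(pos, 0), sex = sex)
        }
      }
    }
  }
  unique(forms)
}

# classify one focal side by exhaustive enumeration
oracle_classify <- function(dam, sire, focal, origin_map, zfd = FALSE) {
  slots <- if (focal == "dam") dam else sire
  if (!all(slots > 0)) {
    pos <- slots[slots > 0]
    if (length(pos) == 1 && any(slots == 0) &&
        (origin_map[[as.character(pos)]] %||% "UNK") %in% c("AUS", "TIM")) {
      return("uninformative") # heterozygous-with-null focal
    }
    return("not_focal")
  }
  orgs <- c(origin_map[[as.character(slots[1])]] %||% "UNK",
            origin_map[[as.character(slots[2])]] %||% "UNK")
  if (!setequal(orgs, c("AUS", "TIM")) || slots[1] == slots[2]) {
    return("not_focal")
  }
  res <- vapply(oracle_forms(dam, sire, zfd), function(f) {
    oracle_deduce(f$off, dam, sire, focal, origin_map, zfd, f$sex)
  }, character(1))
  if (all(res %in% c("0", "1"))) return("fully_informative")
  dp <- dam[dam > 0]; sp <- sire[sire > 0]
  if (length(dp) == 2 && length(sp) == 2 && dam[1] != dam[2] &&
      setequal(dp, sp)) return("partial_ABxAB")
  "uninformative"
}

# ---- brute-force GLMM marginal likelihood ----------------------------------
oracle_glmm_ll <- function(beta, sigma, counts, p0, level_beta = NULL) {
  off <- stats::qlogis(p0)
  if (sigma < 1e-10) sigma <- 1e-10
  ll <- 0
  for (gname in unique(counts$group)) {
    rows <- which(counts$group == gname)
    f <- function(u) {
      sapply(u, function(ui) {
        lp <- 0
        for (r in rows) {
          b <- if (is.null(level_beta)) beta else
            level_beta[[as.character(counts$level[r])]]
          lp <- lp + stats::dbinom(counts$successes[r], counts$n[r],
                                   stats::plogis(off + b + ui), log = TRUE)
        }
        exp(lp) * stats::dnorm(ui, 0, sigma)
      })
    }
    ll <- ll + log(stats::integrate(f, -10 * sigma, 10 * sigma,
                                    rel.tol = 1e-12)$value)
  }
  ll
}

# ---- tiny dataset builders --------------------------------------------------
trio_markers <- function() {
  data.frame(marker_id = c("m1", "m2"), chromosome = c("c1", "c2"),
             position_class = c("centromeric", "distal"),
             cm_from_centromere = c(0, 50), is_z_linked = FALSE,
             stringsAsFactors = FALSE)
}

# A minimal pedigree with one F1 hybrid dam x pure AUS sire brood at a single
# marker. Founder genotypes are constructed to put `aus_alleles` in the
# Australian pool and `tim_alleles` in the Timor pool, so the origin registry
# built from the dataset matches the intended labels. Genotypes may be NULL
# (no record) for an offspring.
make_family_dataset <- function(dam_g, sire_g, kid_gs, marker = "m1",
                                kid_sexes = NULL,
                                aus_alleles = c(200, 202, 220, 222, 230, 232),
                                tim_alleles = c(210, 212)) {
  n <- length(kid_gs)
  if (is.null(kid_sexes)) kid_sexes <- rep("M", n)
  pair_up <- function(x) {
    if (length(x) %% 2 == 1) x <- c(x, x[1])
    split(x, rep(seq_len(length(x) / 2), each = 2))
  }
  aus_pairs <- pair_up(aus_alleles)
  tim_pairs <- pair_up(tim_alleles)
  founders <- data.frame(
    individual_id = c(paste0("AF", seq_along(aus_pairs)),
                      paste0("TF", seq_along(tim_pairs))),
    sex = "M",
    dam_id = NA_character_, sire_id = NA_character_,
    cohort = c(rep("FOUNDER_AUS", length(aus_pairs)),
               rep("FOUNDER_TIM", length(tim_pairs))),
    fate = "adult", stringsAsFactors = FALSE)
  ped <- rbind(
    founders,
    data.frame(individual_id = c("DAM0", "SIRE0"), sex = c("F", "M"),
               dam_id = NA_character_, sire_id = NA_character_,
               cohort = c("FOUNDER_TIM", "FOUNDER_AUS"), fate = "adult",
               stringsAsFactors = FALSE),
    data.frame(individual_id = "F1a", sex = "F", dam_id = "DAM0",
               sire_id = "SIRE0", cohort = "F1", fate = "adult",
               stringsAsFactors = FALSE),
    data.frame(individual_id = "A3", sex = "M", dam_id = NA_character_,
               sire_id = NA_character_, cohort = "FOUNDER_AUS",
               fate = "adult", stringsAsFactors = FALSE),
    data.frame(individual_id = paste0("K", seq_len(n)), sex = kid_sexes,
               dam_id = "F1a", sire_id = "A3", cohort = "BC1",
               fate = "sampled_embryo", stringsAsFactors = FALSE))
  grow <- function(id, g) {
    data.frame(individual_id = id, marker_id = marker,
               allele1 = max(g), allele2 = min(g), stringsAsFactors = FALSE)
  }
  geno <- rbind(
    do.call(rbind, lapply(seq_along(aus_pairs), function(i)
      grow(paste0("AF", i), aus_pairs[[i]]))),
    do.call(rbind, lapply(seq_along(tim_pairs), function(i)
      grow(paste0("TF", i), tim_pairs[[i]]))),
    grow("DAM0", tim_alleles[1:2]),
    grow("SIRE0", aus_alleles[1:2]),
    grow("F1a", dam_g),
    grow("A3", sire_g),
    do.call(rbind, lapply(seq_len(n), function(i) {
      if (is.null(kid_gs[[i]])) return(NULL)
      grow(paste0("K", i), kid_gs[[i]])
    }))
  )
  mk <- data.frame(marker_id = marker, chromosome = "c1",
                   position_class = "centromeric", cm_from_centromere = 0,
                   is_z_linked = FALSE, stringsAsFactors = FALSE)
  new_dataset(ped, geno, mk, validate = FALSE)
}

# quick small cross config for tests
small_cross <- function(seed = 1, ...) {
  cross_config(n_f1 = 6L, f1_males = 4L, n_bc1_eggs = 80L,
               n_bc1_adults = 16L, bc1_adult_males = 8L,
               n_bc1_breeders_m = 6L, n_bc1_breeders_f = 6L,
               n_bc2_eggs = 160L, n_bc2_adults = 20L,
               n_founders_aus = 24L, seed = seed, ...)
}
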