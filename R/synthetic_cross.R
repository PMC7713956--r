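# Forward simulator of the backcross breeding design: ZW meiosis with
# configurable centromeric (meiosis I) and distal (meiosis II) drive,
# producing a drive_dataset plus a truth log so every downstream stage can be
# validated against ground truth.
#
# Origin coding throughout: 1 = Australian (AUS), 0 = Timor (TIM).

#' Default marker map of the simulated genome
#'
#' 29 chromosomes each carry one centromere-linked marker (at most 27 cM from
#' the centromere, median 0 cM) and 27 of them also carry a distal marker (at
#' least 18 cM from the centromere, median 50 cM); the minimum distance
#' between the two markers of a chromosome is 17 cM. One chromosome (`chrZ`)
#' is the Z sex chromosome. Distal distances below 50 cM sit on the
#' submetacentric chromosomes, where there is not always one crossover per
#' chromosome arm.
#'
#' @return Marker map data frame (`marker_id`, `chromosome`,
#'   `position_class`, `cm_from_centromere`, `is_z_linked`).
#' @export
default_marker_map <- function() {
  chroms <- c(sprintf("chr%02d", 1:28), "chrZ")
  dist_cm <- stats::setNames(rep(50, length(chroms)), chroms)
  dist_cm[c("chr01", "chr02", "chr03", "chr04", "chr05", "chr06", "chrZ")] <-
    c(18, 22, 27, 33, 38, 47, 44)
  dist_cm[c("chr27", "chr28")] <- NA # no distal marker on the two smallest
  cen_cm <- stats::setNames(rep(0, length(chroms)), chroms)
  cen_cm[c("chr07", "chr08", "chr10", "chr12", "chr14", "chr16",
           "chr18", "chr20")] <- c(3, 6, 9, 13, 17, 21, 24, 27)
  rows <- list()
  for (ch in chroms) {
    rows[[length(rows) + 1L]] <- data.frame(
      marker_id = paste0(ch, "_cen"), chromosome = ch,
      position_class = "centromeric", cm_from_centromere = cen_cm[[ch]],
      is_z_linked = ch == "chrZ", stringsAsFactors = FALSE)
    if (!is.na(dist_cm[[ch]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = paste0(ch, "_dist"), chromosome = ch,
        position_class = "distal", cm_from_centromere = dist_cm[[ch]],
        is_z_linked = ch == "chrZ", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Specify segregation drive for the simulator
#'
#' @param chromosome Chromosome id or `"all"`.
#' @param parent_sex `"F"` (chromosomal drive is female-specific; requesting
#'   a male bias raises a configuration error in [cross_config()]).
#' @param stage `"MI_centromere"` (biased homolog retention in meiosis I) or
#'   `"MII_distal"` (biased chromatid retention in meiosis II when the
#'   secondary oocyte is heterozygous at the distal locus).
#' @param d Probability that the Australian-origin centromere/chromatid is
#'   retained in the oocyte; 0.5 is fair.
#' @return One-row data frame to be stacked into `cross_config(drive = ...)`.
#' @export
drive_spec <- function(chromosome = "all", parent_sex = "F",
                       stage = c("MI_centromere", "MII_distal"), d = 0.5) {
  stage <- match.arg(stage)
  data.frame(chromosome = chromosome, parent_sex = parent_sex, stage = stage,
             d = d, stringsAsFactors = FALSE)
}

#' Simulator configuration
#'
#' Defaults reproduce the structure of the study design this package
#' emulates: 2 contributing Timor founders, 11 F1 hybrids (7 males, 4
#' females), 51 BC1 adults (26 m, 25 f) among 443 BC1-generation eggs, 41
#' BC1 breeders (18 m, 23 f) and 905 BC2-generation eggs; 56 markers (29
#' centromeric, 27 distal); ~12% apparently infertile eggs; fair segregation
#' everywhere (`d = 0.5`).
#'
#' @param markers Marker map (default [default_marker_map()]).
#' @param n_alleles_aus,n_alleles_tim Founder allele-pool sizes per locus
#'   (disjoint length sets unless `allele_overlap > 0`).
#' @param allele_overlap Probability that a Timor pool allele is replaced by
#'   an Australian length (shared allele -> AMBIG in the registry).
#' @param drive Data frame of [drive_spec()] rows (default: fair).
#' @param crossover Crossover model: `list(model = "obligate_one")` (one
#'   crossover per bivalent, complete interference, Morgan mapping r = d/100)
#'   or `list(model = "poisson")` (no interference, Haldane mapping).
#' @param null_allele_rate Per-(individual, marker) allelic dropout rate.
#' @param infertile_egg_rate Fraction of eggs without embryo development.
#' @param abnormality_rates Named rates for `tetraploidy`, `triploidy`,
#'   `haploidy`, `trisomy`, `monosomy`.
#' @param mechanism_mix Mix of `MI`, `MII`, `polyspermy` mechanisms for
#'   maternal/paternal extra chromosome sets.
#' @param inbreeding_penalty Reduction in the probability that an offspring
#'   homozygous identical-by-descent for an Australian allele is among the
#'   surviving adults (0 = off, 1 = such offspring never survive).
#' @param n_f1,f1_males,n_bc1_eggs,n_bc1_adults,bc1_adult_males,
#'   n_bc1_breeders_m,n_bc1_breeders_f,n_bc2_eggs,n_bc2_adults Cohort sizes.
#' @param n_founders_aus,n_founders_tim,n_tim_contributing Founder counts.
#' @param founder_introgression Diploid admixed fraction of the Timor founder
#'   genome carried as heterozygous Australian tracts (used by
#'   [simulate_founder_sites()]).
#' @param seed Root seed; all stage streams derive from it.
#' @return Object of class `cross_config`.
#' @export
cross_config <- function(markers = default_marker_map(),
                         n_alleles_aus = 6L, n_alleles_tim = 2L,
                         allele_overlap = 0,
                         drive = NULL,
                         crossover = list(model = "obligate_one"),
                         null_allele_rate = 0.02,
                         infertile_egg_rate = 0.12,
                         abnormality_rates = c(tetraploidy = 0.003,
                                               triploidy = 0.008,
                                               haploidy = 0.004,
                                               trisomy = 0.009,
                                               monosomy = 0.005),
                         mechanism_mix = c(MI = 0.5, MII = 0.2,
                                           polyspermy = 0.3),
                         inbreeding_penalty = 0,
                         n_f1 = 11L, f1_males = 7L,
                         n_bc1_eggs = 443L, n_bc1_adults = 51L,
                         bc1_adult_males = 26L,
                         n_bc1_breeders_m = 18L, n_bc1_breeders_f = 23L,
                         n_bc2_eggs = 905L, n_bc2_adults = 79L,
                         n_founders_aus = 60L, n_founders_tim = 4L,
                         n_tim_contributing = 2L,
                         founder_introgression = 0.0478,
                         seed = 1L) {
  if (is.null(drive)) drive <- drive_spec()[0, ]
  cfg <- list(markers = markers, n_alleles_aus = n_alleles_aus,
              n_alleles_tim = n_alleles_tim, allele_overlap = allele_overlap,
              drive = drive, crossover = crossover,
              null_allele_rate = null_allele_rate,
              infertile_egg_rate = infertile_egg_rate,
              abnormality_rates = abnormality_rates,
              mechanism_mix = mechanism_mix,
              inbreeding_penalty = inbreeding_penalty,
              n_f1 = n_f1, f1_males = f1_males,
              n_bc1_eggs = n_bc1_eggs, n_bc1_adults = n_bc1_adults,
              bc1_adult_males = bc1_adult_males,
              n_bc1_breeders_m = n_bc1_breeders_m,
              n_bc1_breeders_f = n_bc1_breeders_f,
              n_bc2_eggs = n_bc2_eggs, n_bc2_adults = n_bc2_adults,
              n_founders_aus = n_founders_aus,
              n_founders_tim = n_founders_tim,
              n_tim_contributing = n_tim_contributing,
              founder_introgression = founder_introgression,
              seed = seed)
  class(cfg) <- "cross_config"
  validate_cross_config(cfg)
  cfg
}

validate_cross_config <- function(cfg) {
  probs <- c(cfg$allele_overlap, cfg$null_allele_rate,
             cfg$infertile_egg_rate, cfg$abnormality_rates,
             cfg$inbreeding_penalty, cfg$founder_introgression)
  if (any(probs < 0 | probs > 1)) {
    stop_fmt("configuration error: all rates/probabilities must lie in [0, 1]")
  }
  sizes <- c(cfg$n_f1, cfg$n_bc1_eggs, cfg$n_bc2_eggs, cfg$n_founders_aus,
             cfg$n_founders_tim)
  if (any(sizes < 1)) stop_fmt("configuration error: cohort sizes must be positive")
  if (cfg$f1_males > cfg$n_f1) stop_fmt("configuration error: f1_males > n_f1")
  d <- cfg$drive
  if (nrow(d)) {
    if (any(d$d < 0 | d$d > 1)) stop_fmt("configuration error: drive d outside [0, 1]")
    male_bias <- d$parent_sex == "M" & d$d != 0.5
    if (any(male_bias)) {
      stop_fmt(paste("configuration error: chromosomal drive is female-specific",
                     "(asymmetric female meiosis); male biases are post-meiotic",
                     "and out of scope"))
    }
  }
  if (!cfg$crossover$model %in% c("obligate_one", "poisson")) {
    stop_fmt("configuration error: unknown crossover model '%s'",
             cfg$crossover$model)
  }
  # partner arithmetic: every hybrid breeder needs a distinct pure partner
  needed <- 2L + cfg$n_f1 + cfg$n_bc1_breeders_m + cfg$n_bc1_breeders_f
  if (needed > cfg$n_founders_aus) {
    stop_fmt("configuration error: %d Australian founders needed as parents/partners but only %d configured",
             needed, cfg$n_founders_aus)
  }
  invisible(cfg)
}

# Resolve the drive table into per-chromosome d vectors for female meiosis.
resolve_drive <- function(drive, chroms) {
  d_mi <- stats::setNames(rep(0.5, length(chroms)), chroms)
  d_mii <- d_mi
  if (nrow(drive)) {
    for (i in seq_len(nrow(drive))) {
      if (drive$parent_sex[i] != "F") next
      target <- if (drive$chromosome[i] == "all") chroms else drive$chromosome[i]
      if (drive$stage[i] == "MI_centromere") d_mi[target] <- drive$d[i]
      else d_mii[target] <- drive$d[i]
    }
  }
  list(mi = d_mi, mii = d_mii)
}

# Per-chromosome map geometry used by the meiosis engine.
chrom_geometry <- function(markers) {
  chroms <- unique(markers$chromosome)
  pc <- pd <- stats::setNames(rep(NA_real_, length(chroms)), chroms)
  for (i in seq_len(nrow(markers))) {
    ch <- markers$chromosome[i]
    if (markers$position_class[i] == "centromeric") {
      pc[ch] <- markers$cm_from_centromere[i]
    } else {
      pd[ch] <- markers$cm_from_centromere[i]
    }
  }
  pc[is.na(pc)] <- 0
  list(chroms = chroms, pc = pc, pd = pd,
       zrow = match(TRUE, startsWith(chroms, "chrZ") |
                      markers$is_z_linked[match(chroms, markers$chromosome)]))
}

# Vectorised meiosis for one parent: n gametes at once.
# Haplotype slices are vectors over chromosomes; returns matrices
# [n_chrom x n] plus per-gamete W flags and truth fields.
meiosis_engine <- function(h1, h2, sex, n, geom, d_mi, d_mii, crossover,
                           force_w = NULL) {
  nc <- length(geom$chroms)
  pc <- geom$pc; pd <- geom$pd
  co1 <- h1$co; co2 <- h2$co
  p1 <- ifelse(!is.na(co1) & !is.na(co2) & co1 == 1 & co2 == 0, d_mi,
               ifelse(!is.na(co1) & !is.na(co2) & co1 == 0 & co2 == 1,
                      1 - d_mi, 0.5))
  if (sex == "M") p1 <- rep(0.5, nc)
  R1 <- matrix(stats::runif(nc * n) < p1, nc, n)
  pick <- function(a, b) ifelse(R1, a, b) # retained homolog fields
  ret <- list(cen_al = pick(h1$cen_al, h2$cen_al),
              dist_al = pick(h1$dist_al, h2$dist_al),
              cen_or = pick(h1$cen_or, h2$cen_or),
              dist_or = pick(h1$dist_or, h2$dist_or),
              co = pick(h1$co, h2$co))
  oth <- list(cen_al = pick(h2$cen_al, h1$cen_al),
              dist_al = pick(h2$dist_al, h1$dist_al),
              cen_or = pick(h2$cen_or, h1$cen_or),
              dist_or = pick(h2$dist_or, h1$dist_or))
  if (crossover$model == "obligate_one") {
    # one crossover per bivalent, position uniform on the 50 cM bundle;
    # sister 2 carries the exchanged segment
    x <- matrix(stats::runif(nc * n) * 50, nc, n)
    sw_cen2 <- pc > x
    sw_dist2 <- pd > x # NA where no distal marker
    sw_cen1 <- matrix(FALSE, nc, n)
    sw_dist1 <- matrix(FALSE, nc, n)
  } else {
    # no-interference model: per-chromatid Poisson crossover counts; a locus
    # toggles ancestry when an odd number of exchanges occurred below it
    x <- matrix(NA_real_, nc, n)
    span <- ifelse(is.na(pd), pc, pd)
    n1a <- matrix(stats::rpois(nc * n, pc / 100), nc, n)
    n2a <- matrix(stats::rpois(nc * n, pmax(span - pc, 0) / 100), nc, n)
    n1b <- matrix(stats::rpois(nc * n, pc / 100), nc, n)
    n2b <- matrix(stats::rpois(nc * n, pmax(span - pc, 0) / 100), nc, n)
    sw_cen1 <- n1a %% 2 == 1
    sw_dist1 <- (n1a + n2a) %% 2 == 1
    sw_cen2 <- n1b %% 2 == 1
    sw_dist2 <- (n1b + n2b) %% 2 == 1
    sw_dist1[is.na(pd), ] <- NA
    sw_dist2[is.na(pd), ] <- NA
  }
  sister <- function(swc, swd) {
    list(cen_al = ifelse(swc, oth$cen_al, ret$cen_al),
         dist_al = ifelse(swd, oth$dist_al, ret$dist_al),
         cen_or = ifelse(swc, oth$cen_or, ret$cen_or),
         dist_or = ifelse(swd, oth$dist_or, ret$dist_or))
  }
  s1 <- sister(sw_cen1, sw_dist1)
  s2 <- sister(sw_cen2, sw_dist2)
  # meiosis II: biased chromatid retention only when the secondary oocyte is
  # heterozygous by origin at the distal locus
  het <- !is.na(s1$dist_or) & !is.na(s2$dist_or) & s1$dist_or != s2$dist_or
  pch1 <- ifelse(het, ifelse(s1$dist_or == 1, d_mii, 1 - d_mii), 0.5)
  if (sex == "M") pch1[] <- 0.5
  C1 <- matrix(stats::runif(nc * n), nc, n) < pch1
  g <- list(cen_al = ifelse(C1, s1$cen_al, s2$cen_al),
            dist_al = ifelse(C1, s1$dist_al, s2$dist_al),
            cen_or = ifelse(C1, s1$cen_or, s2$cen_or),
            dist_or = ifelse(C1, s1$dist_or, s2$dist_or),
            co = ret$co, x = x)
  is_w <- rep(FALSE, n)
  zr <- geom$zrow
  if (sex == "F" && !is.na(zr)) {
    # ZW female: no Z-W recombination, no drive; the Z haplotype is whichever
    # carries observable alleles at the Z row
    zhap <- if (!is.na(h1$cen_al[zr]) && h1$cen_al[zr] > 0) h1 else h2
    is_w <- if (is.null(force_w)) stats::runif(n) < 0.5 else force_w
    g$cen_al[zr, ] <- ifelse(is_w, W_PLACEHOLDER, zhap$cen_al[zr])
    g$dist_al[zr, ] <- ifelse(is_w, W_PLACEHOLDER, zhap$dist_al[zr])
    g$cen_or[zr, ] <- ifelse(is_w, NA, zhap$cen_or[zr])
    g$dist_or[zr, ] <- ifelse(is_w, NA, zhap$dist_or[zr])
    g$co[zr, ] <- ifelse(is_w, NA, zhap$co[zr])
    g$x[zr, ] <- NA
  }
  g$is_w <- is_w
  g
}

#' Simulate meioses of a single parent
#'
#' Runs the gamete engine for one parent and returns the transmitted
#' haplotypes. In females, meiosis I retains the Australian-origin centromere
#' of an origin-heterozygous chromosome with probability `d_MI`, marker
#' alleles travel with the chromatid they sit on given simulated crossovers,
#' and meiosis II retains the Australian-origin chromatid with probability
#' `d_MII` when the retained secondary oocyte is heterozygous at the distal
#' locus. Male meiosis is symmetric (both probabilities forced to 0.5); W vs
#' Z transmission in females is fair.
#'
#' @param parent List with haplotypes `hap1`, `hap2`, each a list of vectors
#'   over chromosomes: `cen_al`, `dist_al` (allele lengths), `cen_or`,
#'   `dist_or` (1 = AUS, 0 = TIM), `co` (origin at the centromere itself).
#' @param parent_sex `"F"` or `"M"`.
#' @param markers Marker map defining the chromosome geometry.
#' @param drive Drive table from [drive_spec()] rows.
#' @param crossover Crossover model (see [cross_config()]).
#' @param n Number of gametes.
#' @param seed Seed for this batch.
#' @return List of `[n_chrom x n]` matrices (`cen_al`, `dist_al`, `cen_or`,
#'   `dist_or`, `co`, `x` crossover position) plus `is_w` (length `n`).
#' @export
simulate_meiosis <- function(parent, parent_sex, markers = default_marker_map(),
                             drive = drive_spec()[0, ],
                             crossover = list(model = "obligate_one"),
                             n = 1L, seed = 1L) {
  if (nrow(drive) && any(drive$parent_sex == "M" & drive$d != 0.5)) {
    stop_fmt("configuration error: chromosomal drive is female-specific")
  }
  geom <- chrom_geometry(markers)
  dd <- resolve_drive(drive, geom$chroms)
  set.seed(seed)
  meiosis_engine(parent$hap1, parent$hap2, parent_sex, n, geom,
                 dd$mi, dd$mii, crossover)
}

#' Marginal transmission sampler for calibration studies
#'
#' At a marker with recombination fraction `r` to the driven centromere, the
#' marginal probability that a gamete carries the Australian allele of an
#' origin-heterozygous parent is `d (1 - r) + (1 - d) r`. This sampler draws
#' per-marker success counts directly from that marginal (it is exactly the
#' per-transmission law of the full meiosis engine, which tests verify) so
#' that large calibration experiments are cheap.
#'
#' @param n_markers Number of markers.
#' @param n_per_marker Informative transmissions per marker (scalar or
#'   vector).
#' @param d Meiosis-I retention probability of the Australian centromere.
#' @param r Recombination fraction between marker and centromere.
#' @param seed Seed.
#' @return Integer vector of Australian-transmission counts per marker.
#' @export
simulate_transmission_counts <- function(n_markers, n_per_marker, d = 0.5,
                                         r = 0, seed = 1L) {
  set.seed(seed)
  p <- d * (1 - r) + (1 - d) * r
  stats::rbinom(n_markers, n_per_marker, p)
}

# ---- full cross -------------------------------------------------------------

# Build founder allele pools: disjoint AUS/TIM length sets per marker, with
# optional sharing.
build_allele_pools <- function(cfg) {
  mk <- cfg$markers
  pools <- vector("list", nrow(mk))
  names(pools) <- mk$marker_id
  for (i in seq_len(nrow(mk))) {
    base <- 100L + 4L * i
    aus <- base + 2L * seq_len(cfg$n_alleles_aus) - 2L
    tim <- base + 2L * (cfg$n_alleles_aus + seq_len(cfg$n_alleles_tim)) - 2L
    if (cfg$allele_overlap > 0) {
      share <- stats::runif(length(tim)) < cfg$allele_overlap
      if (any(share)) tim[share] <- sample(aus, sum(share), replace = TRUE)
      tim <- unique(tim)
    }
    pools[[i]] <- list(AUS = aus, TIM = tim)
  }
  pools
}

new_population <- function(n_total, geom) {
  nc <- length(geom$chroms)
  list(
    id = character(n_total), sex = character(n_total),
    cohort = character(n_total), dam = rep(NA_character_, n_total),
    sire = rep(NA_character_, n_total), fate = rep("adult", n_total),
    cen_al = array(NA_real_, c(nc, 2, n_total)),
    dist_al = array(NA_real_, c(nc, 2, n_total)),
    cen_or = array(NA_real_, c(nc, 2, n_total)),
    dist_or = array(NA_real_, c(nc, 2, n_total)),
    co = array(NA_real_, c(nc, 2, n_total))
  )
}

hap_of <- function(pop, idx, h) {
  list(cen_al = pop$cen_al[, h, idx], dist_al = pop$dist_al[, h, idx],
       cen_or = pop$cen_or[, h, idx], dist_or = pop$dist_or[, h, idx],
       co = pop$co[, h, idx])
}

# Fill one founder's haplotypes by sampling the pool of its origin.
sample_founder <- function(pop, idx, origin, sex, pools, geom, mk) {
  orig_code <- if (origin == "AUS") 1 else 0
  nc <- length(geom$chroms)
  for (h in 1:2) {
    for (i in seq_len(nrow(mk))) {
      ch <- match(mk$chromosome[i], geom$chroms)
      al <- sample(pools[[mk$marker_id[i]]][[origin]], 1L)
      if (mk$position_class[i] == "centromeric") {
        pop$cen_al[ch, h, idx] <- al
        pop$cen_or[ch, h, idx] <- orig_code
      } else {
        pop$dist_al[ch, h, idx] <- al
        pop$dist_or[ch, h, idx] <- orig_code
      }
    }
    pop$co[, h, idx] <- orig_code
  }
  zr <- geom$zrow
  if (sex == "F" && !is.na(zr)) {
    # haplotype 1 is the W at the Z row
    pop$cen_al[zr, 1, idx] <- W_PLACEHOLDER
    pop$dist_al[zr, 1, idx] <- W_PLACEHOLDER
    pop$cen_or[zr, 1, idx] <- NA
    pop$dist_or[zr, 1, idx] <- NA
    pop$co[zr, 1, idx] <- NA
  }
  pop
}

#' Simulate the full backcross design
#'
#' Builds founders from origin-disjoint allele pools, produces the F1 by
#' hybridizing the two contributing Timor founders with Australian partners,
#' backcrosses the F1 and then the BC1 adults to further Australian
#' partners, and applies the nuisance processes (infertile eggs, adult
#' survival with optional inbreeding penalty, null alleles, chromosomal
#' abnormalities). Offspring sex follows the maternal Z/W gamete.
#'
#' @param cfg A [cross_config()].
#' @param nuisance Apply genotype-level nuisances (null alleles,
#'   abnormalities) via [inject_nuisance()] (default `TRUE`). Infertile eggs
#'   and survival fates are part of the breeding design and always applied.
#' @return Object of class `cross_sim`: list with `dataset` (a
#'   `drive_dataset`), `truth` (a `truth_log`: `meioses` and `events` data
#'   frames) and `config`.
#' @export
simulate_cross <- function(cfg = cross_config(), nuisance = TRUE) {
  validate_cross_config(cfg)
  mk <- cfg$markers
  geom <- chrom_geometry(mk)
  dd <- resolve_drive(cfg$drive, geom$chroms)
  nc <- length(geom$chroms)

  set.seed(derive_seed(cfg$seed, "pools"))
  pools <- build_allele_pools(cfg)

  n_total <- cfg$n_founders_aus + cfg$n_founders_tim + cfg$n_f1 +
    cfg$n_bc1_eggs + cfg$n_bc2_eggs
  pop <- new_population(n_total, geom)
  cursor <- 0L
  claim <- function(n) {
    idx <- cursor + seq_len(n)
    cursor <<- cursor + n
    idx
  }

  # founders ------------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "founders"))
  aus_idx <- claim(cfg$n_founders_aus)
  tim_idx <- claim(cfg$n_founders_tim)
  half <- ceiling(cfg$n_founders_aus / 2)
  for (j in seq_along(aus_idx)) {
    i <- aus_idx[j]
    sex <- if (j <= half) "M" else "F"
    pop$id[i] <- sprintf("AUS%03d", j)
    pop$sex[i] <- sex
    pop$cohort[i] <- "FOUNDER_AUS"
    pop <- sample_founder(pop, i, "AUS", sex, pools, geom, mk)
  }
  for (j in seq_along(tim_idx)) {
    i <- tim_idx[j]
    sex <- if (j %% 2 == 1) "M" else "F"
    pop$id[i] <- sprintf("TIM%03d", j)
    pop$sex[i] <- sex
    pop$cohort[i] <- "FOUNDER_TIM"
    pop <- sample_founder(pop, i, "TIM", sex, pools, geom, mk)
  }
  aus_m <- aus_idx[pop$sex[aus_idx] == "M"]
  aus_f <- aus_idx[pop$sex[aus_idx] == "F"]
  used_m <- used_f <- 0L
  next_aus <- function(sex) {
    if (sex == "M") {
      used_m <<- used_m + 1L
      aus_m[used_m]
    } else {
      used_f <<- used_f + 1L
      aus_f[used_f]
    }
  }
  tim_m <- tim_idx[pop$sex[tim_idx] == "M"][1]
  tim_f <- tim_idx[pop$sex[tim_idx] == "F"][1]

  truth_chunks <- list()
  log_meioses <- function(kid_idx, par_idx, g) {
    n <- length(kid_idx)
    truth_chunks[[length(truth_chunks) + 1L]] <<- data.frame(
      offspring_id = rep(pop$id[kid_idx], each = nc),
      parent_id = pop$id[par_idx],
      parent_sex = pop$sex[par_idx],
      chromosome = rep(geom$chroms, times = n),
      homolog_retained = ifelse(is.na(as.vector(g$co)), "W",
                                ifelse(as.vector(g$co) == 1, "AUS", "TIM")),
      crossover_cM = as.vector(g$x),
      cen_allele = as.vector(g$cen_al),
      cen_origin = as.vector(g$cen_or),
      dist_allele = as.vector(g$dist_al),
      dist_origin = as.vector(g$dist_or),
      parent_het_cen = rep(parent_origin_het(pop, par_idx, "cen"), times = n),
      parent_het_dist = rep(parent_origin_het(pop, par_idx, "dist"), times = n),
      stringsAsFactors = FALSE)
  }

  breed <- function(dam_idx, sire_idx, kid_idx, kid_prefix, cohort,
                    force_w = NULL, stream = "") {
    n <- length(kid_idx)
    set.seed(derive_seed(cfg$seed, paste0("meiosis-", stream, pop$id[dam_idx])))
    gm <- meiosis_engine(hap_of(pop, dam_idx, 1), hap_of(pop, dam_idx, 2),
                         "F", n, geom, dd$mi, dd$mii, cfg$crossover, force_w)
    set.seed(derive_seed(cfg$seed, paste0("meiosis-", stream, pop$id[sire_idx])))
    gp <- meiosis_engine(hap_of(pop, sire_idx, 1), hap_of(pop, sire_idx, 2),
                         "M", n, geom, dd$mi, dd$mii, cfg$crossover)
    pop$id[kid_idx] <<- sprintf("%s%04d", kid_prefix, seq_along(kid_idx) +
                                  attr(kid_prefix, "offset") %||% 0L)
    pop$sex[kid_idx] <<- ifelse(gm$is_w, "F", "M")
    pop$cohort[kid_idx] <<- cohort
    pop$dam[kid_idx] <<- pop$id[dam_idx]
    pop$sire[kid_idx] <<- pop$id[sire_idx]
    pop$cen_al[, 1, kid_idx] <<- gm$cen_al
    pop$dist_al[, 1, kid_idx] <<- gm$dist_al
    pop$cen_or[, 1, kid_idx] <<- gm$cen_or
    pop$dist_or[, 1, kid_idx] <<- gm$dist_or
    pop$co[, 1, kid_idx] <<- gm$co
    pop$cen_al[, 2, kid_idx] <<- gp$cen_al
    pop$dist_al[, 2, kid_idx] <<- gp$dist_al
    pop$cen_or[, 2, kid_idx] <<- gp$cen_or
    pop$dist_or[, 2, kid_idx] <<- gp$dist_or
    pop$co[, 2, kid_idx] <<- gp$co
    log_meioses(kid_idx, dam_idx, gm)
    log_meioses(kid_idx, sire_idx, gp)
  }

  # F1: Timor male x Australian female, Australian male x Timor female ---
  n1 <- ceiling(cfg$n_f1 / 2)
  n2 <- cfg$n_f1 - n1
  m1 <- min(ceiling(cfg$f1_males * n1 / cfg$n_f1), n1)
  m2 <- cfg$f1_males - m1
  f1_idx <- claim(cfg$n_f1)
  p1_kids <- f1_idx[seq_len(n1)]
  p2_kids <- f1_idx[n1 + seq_len(n2)]
  pre <- "F1_"
  attr(pre, "offset") <- 0L
  breed(next_aus("F"), tim_m, p1_kids, pre, "F1",
        force_w = c(rep(FALSE, m1), rep(TRUE, n1 - m1)), stream = "f1a-")
  attr(pre, "offset") <- n1
  if (n2 > 0) {
    breed(tim_f, next_aus("M"), p2_kids, pre, "F1",
          force_w = c(rep(FALSE, m2), rep(TRUE, n2 - m2)), stream = "f1b-")
  }
  pop$fate[f1_idx] <- "adult"

  # BC1: each F1 x a fresh Australian partner ---------------------------
  bc1_idx <- claim(cfg$n_bc1_eggs)
  per <- rep(floor(cfg$n_bc1_eggs / cfg$n_f1), cfg$n_f1)
  extra <- cfg$n_bc1_eggs - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  off <- 0L
  for (j in seq_along(f1_idx)) {
    fi <- f1_idx[j]
    kid <- bc1_idx[off + seq_len(per[j])]
    partner <- next_aus(if (pop$sex[fi] == "M") "F" else "M")
    dam <- if (pop$sex[fi] == "F") fi else partner
    sire <- if (pop$sex[fi] == "M") fi else partner
    pre <- "BC1_"
    attr(pre, "offset") <- off
    breed(dam, sire, kid, pre, "BC1", stream = "bc1-")
    off <- off + per[j]
  }

  # fates in BC1: infertile eggs, adults (with optional inbreeding penalty)
  set.seed(derive_seed(cfg$seed, "fates-bc1"))
  bc1_fates <- assign_fates(pop, bc1_idx, cfg,
                            n_adult_m = cfg$bc1_adult_males,
                            n_adult_f = cfg$n_bc1_adults - cfg$bc1_adult_males)
  pop$fate[bc1_idx] <- bc1_fates
  pop$sex[bc1_idx[bc1_fates == "infertile_egg"]] <- NA_character_

  # BC2: BC1 breeders x fresh Australian partners ------------------------
  adults_bc1 <- bc1_idx[pop$fate[bc1_idx] == "adult"]
  br_m <- adults_bc1[pop$sex[adults_bc1] == "M"][seq_len(cfg$n_bc1_breeders_m)]
  br_f <- adults_bc1[pop$sex[adults_bc1] == "F"][seq_len(cfg$n_bc1_breeders_f)]
  breeders <- c(br_m, br_f)
  if (anyNA(breeders)) {
    stop_fmt("configuration error: not enough surviving BC1 adults of each sex to form %d + %d breeding pairs",
             cfg$n_bc1_breeders_m, cfg$n_bc1_breeders_f)
  }
  bc2_idx <- claim(cfg$n_bc2_eggs)
  nb <- length(breeders)
  per <- rep(floor(cfg$n_bc2_eggs / nb), nb)
  extra <- cfg$n_bc2_eggs - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  off <- 0L
  for (j in seq_along(breeders)) {
    bi <- breeders[j]
    kid <- bc2_idx[off + seq_len(per[j])]
    partner <- next_aus(if (pop$sex[bi] == "M") "F" else "M")
    dam <- if (pop$sex[bi] == "F") bi else partner
    sire <- if (pop$sex[bi] == "M") bi else partner
    pre <- "BC2_"
    attr(pre, "offset") <- off
    breed(dam, sire, kid, pre, "BC2", stream = "bc2-")
    off <- off + per[j]
  }
  set.seed(derive_seed(cfg$seed, "fates-bc2"))
  bc2_fates <- assign_fates(pop, bc2_idx, cfg, n_adult_any = cfg$n_bc2_adults)
  pop$fate[bc2_idx] <- bc2_fates
  pop$sex[bc2_idx[bc2_fates == "infertile_egg"]] <- NA_character_

  # assemble dataset ------------------------------------------------------
  all_idx <- seq_len(cursor)
  individuals <- data.frame(
    individual_id = pop$id[all_idx], sex = pop$sex[all_idx],
    dam_id = pop$dam[all_idx], sire_id = pop$sire[all_idx],
    cohort = pop$cohort[all_idx], fate = pop$fate[all_idx],
    stringsAsFactors = FALSE)
  genotyped <- all_idx[pop$fate[all_idx] != "infertile_egg"]
  geno <- assemble_genotypes(pop, genotyped, mk, geom)
  ds <- new_dataset(individuals, geno, mk, validate = FALSE)
  truth <- structure(list(
    meioses = do.call(rbind, truth_chunks),
    events = infertility_events(pop, c(bc1_idx, bc2_idx))
  ), class = "truth_log")
  sim <- structure(list(dataset = ds, truth = truth, config = cfg),
                   class = "cross_sim")
  if (nuisance) {
    sim <- inject_nuisance(sim$dataset, sim$truth, cfg,
                           seed = derive_seed(cfg$seed, "nuisance"))
    sim$config <- cfg
  }
  validate_dataset(sim$dataset)
  sim
}

parent_origin_het <- function(pop, idx, which) {
  o1 <- if (which == "cen") pop$cen_or[, 1, idx] else pop$dist_or[, 1, idx]
  o2 <- if (which == "cen") pop$cen_or[, 2, idx] else pop$dist_or[, 2, idx]
  !is.na(o1) & !is.na(o2) & o1 != o2
}

infertility_events <- function(pop, idx) {
  inf <- idx[pop$fate[idx] == "infertile_egg"]
  if (!length(inf)) {
    return(data.frame(individual_id = character(), marker_id = character(),
                      chromosome = character(), event = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  data.frame(individual_id = pop$id[inf], marker_id = NA_character_,
             chromosome = NA_character_, event = "infertile_egg",
             detail = "", stringsAsFactors = FALSE)
}

# Infertility + survivorship fates for one egg cohort. Adults are sampled
# among fertile eggs, down-weighting offspring homozygous identical-by-
# descent for an Australian allele by the inbreeding penalty.
assign_fates <- function(pop, idx, cfg, n_adult_m = 0L, n_adult_f = 0L,
                         n_adult_any = 0L) {
  n <- length(idx)
  fate <- rep("sampled_embryo", n)
  infertile <- stats::runif(n) < cfg$infertile_egg_rate
  fate[infertile] <- "infertile_egg"
  fertile <- which(!infertile)
  # embryo vs chick split among the non-adult fertile eggs (cosmetic)
  chick <- fertile[stats::runif(length(fertile)) < 0.15]
  fate[chick] <- "dead_chick"
  w <- rep(1, n)
  if (cfg$inbreeding_penalty > 0) {
    # per-locus hazard: each marker homozygous identical-by-descent for an
    # Australian allele multiplies the survival weight by (1 - penalty)
    n_ibd <- vapply(idx, function(i) {
      sum(pop$cen_al[, 1, i] == pop$cen_al[, 2, i] &
            pop$cen_or[, 1, i] == 1 & pop$cen_or[, 2, i] == 1, na.rm = TRUE) +
        sum(pop$dist_al[, 1, i] == pop$dist_al[, 2, i] &
              pop$dist_or[, 1, i] == 1 & pop$dist_or[, 2, i] == 1,
            na.rm = TRUE)
    }, numeric(1))
    w <- (1 - cfg$inbreeding_penalty)^n_ibd
  }
  pick_adults <- function(cand, k) {
    if (k == 0L) return(integer())
    if (length(cand) < k) {
      stop_fmt("configuration error: only %d eligible offspring for %d adult slots",
               length(cand), k)
    }
    if (all(w[cand] == w[cand][1])) sample(cand, k)
    else sample(cand, k, prob = pmax(w[cand], 1e-12))
  }
  if (n_adult_any > 0L) {
    fate[pick_adults(fertile, n_adult_any)] <- "adult"
  } else {
    sexes <- pop$sex[idx]
    fate[pick_adults(fertile[sexes[fertile] == "M"], n_adult_m)] <- "adult"
    fate[pick_adults(fertile[sexes[fertile] == "F"], n_adult_f)] <- "adult"
  }
  fate
}

# Long genotype table from the population arrays; stored pairs are ordered
# (larger, smaller) so the W placeholder sorts last.
assemble_genotypes <- function(pop, idx, mk, geom) {
  out <- vector("list", nrow(mk))
  for (i in seq_len(nrow(mk))) {
    ch <- match(mk$chromosome[i], geom$chroms)
    if (mk$position_class[i] == "centromeric") {
      a1 <- pop$cen_al[ch, 1, idx]; a2 <- pop$cen_al[ch, 2, idx]
    } else {
      a1 <- pop$dist_al[ch, 1, idx]; a2 <- pop$dist_al[ch, 2, idx]
    }
    out[[i]] <- data.frame(
      individual_id = pop$id[idx], marker_id = mk$marker_id[i],
      allele1 = as.integer(pmax(a1, a2)), allele2 = as.integer(pmin(a1, a2)),
      allele3 = NA_integer_, allele4 = NA_integer_, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
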