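# ZW meiosis engine, breeding-design simulator and nuisance injection.

# an F1-like parent: homolog 1 fully Australian, homolog 2 fully Timor
f1_parent <- function(markers) {
  chroms <- unique(markers$chromosome)
  nc <- length(chroms)
  mk_hap <- function(or, base) {
    list(cen_al = rep(base, nc), dist_al = rep(base + 1, nc),
         cen_or = rep(or, nc), dist_or = rep(or, nc), co = rep(or, nc))
  }
  list(hap1 = mk_hap(1, 200), hap2 = mk_hap(0, 300))
}

one_chrom_map <- function(cen_cm = 0, dist_cm = 50) {
  data.frame(marker_id = c("c", "d"), chromosome = "c1",
             position_class = c("centromeric", "distal"),
             cm_from_centromere = c(cen_cm, dist_cm),
             is_z_linked = FALSE, stringsAsFactors = FALSE)
}

test_that("MI drive passes through to centromeric transmission frequency", {
  mk <- one_chrom_map()
  par <- f1_parent(mk)
  drv <- drive_spec("all", "F", "MI_centromere", d = 0.8)
  g <- simulate_meiosis(par, "F", mk, drive = drv, n = 1e5, seed = 1)
  freq <- mean(g$cen_or[1, ] == 1)
  se <- sqrt(0.8 * 0.2 / 1e5)
  expect_lt(abs(freq - 0.8), 3 * se)
})

test_that("distal transmission follows d(1-r) + (1-d)r under Morgan mapping", {
  drv <- drive_spec("all", "F", "MI_centromere", d = 0.8)
  for (dist_cm in c(50, 30)) {
    r <- dist_cm / 100 # obligate single crossover: complete interference
    mk <- one_chrom_map(0, dist_cm)
    par <- f1_parent(mk)
    g <- simulate_meiosis(par, "F", mk, drive = drv, n = 1e5, seed = 2)
    expected <- 0.8 * (1 - r) + 0.2 * r
    freq <- mean(g$dist_or[1, ] == 1)
    expect_lt(abs(freq - expected), 3 * sqrt(expected * (1 - expected) / 1e5))
  }
  # at r = 0.5 the distal marker is exactly unlinked from the drive
  mk <- one_chrom_map(0, 50)
  par <- f1_parent(mk)
  g <- simulate_meiosis(par, "F", mk, drive = drv, n = 2e5, seed = 3)
  expect_lt(abs(mean(g$dist_or[1, ] == 1) - 0.5), 3 * sqrt(0.25 / 2e5))
})

test_that("MII distal drive distorts the distal locus but not the centromere", {
  # four-chromatid enumeration under an obligate crossover at x ~ U(0, 50):
  # the secondary oocyte is origin-heterozygous at the distal locus iff
  # x < dist_cm, in which case the AUS chromatid is retained w.p. d_MII
  for (dist_cm in c(50, 30)) {
    p_het <- dist_cm / 50
    expected <- p_het * 0.8 + (1 - p_het) * 0.5
    mk <- one_chrom_map(0, dist_cm)
    par <- f1_parent(mk)
    drv <- drive_spec("all", "F", "MII_distal", d = 0.8)
    g <- simulate_meiosis(par, "F", mk, drive = drv, n = 1e5, seed = 4)
    expect_lt(abs(mean(g$dist_or[1, ] == 1) - expected),
              3 * sqrt(expected * (1 - expected) / 1e5))
    expect_lt(abs(mean(g$cen_or[1, ] == 1) - 0.5), 3 * sqrt(0.25 / 1e5))
  }
})

test_that("male meiosis is always fair and male drive is rejected", {
  mk <- one_chrom_map()
  par <- f1_parent(mk)
  expect_error(
    simulate_meiosis(par, "M", mk,
                     drive = drive_spec("all", "M", "MI_centromere", 0.8)),
    "female-specific")
  expect_error(cross_config(drive = drive_spec("all", "M", "MI_centromere", 0.7)),
               "female-specific")
  # a female drive spec leaves male meiosis at 0.5
  g <- simulate_meiosis(par, "M", mk,
                        drive = drive_spec("all", "F", "MI_centromere", 0.9),
                        n = 5e4, seed = 5)
  expect_lt(abs(mean(g$cen_or[1, ] == 1) - 0.5), 3 * sqrt(0.25 / 5e4))
})

test_that("poisson crossover model reproduces Haldane recombination", {
  for (dist_cm in c(20, 50)) {
    r_hald <- (1 - exp(-2 * dist_cm / 100)) / 2
    mk <- one_chrom_map(0, dist_cm)
    par <- f1_parent(mk)
    g <- simulate_meiosis(par, "F", mk, crossover = list(model = "poisson"),
                          n = 1e5, seed = 6)
    rec <- mean((g$cen_or[1, ] == 1) != (g$dist_or[1, ] == 1))
    expect_lt(abs(rec - r_hald), 3 * sqrt(r_hald * (1 - r_hald) / 1e5))
  }
})

test_that("marginal transmission sampler matches the meiosis engine", {
  mk <- one_chrom_map(0, 30)
  par <- f1_parent(mk)
  drv <- drive_spec("all", "F", "MI_centromere", d = 0.7)
  g <- simulate_meiosis(par, "F", mk, drive = drv, n = 1e5, seed = 7)
  engine <- mean(g$dist_or[1, ] == 1)
  s <- simulate_transmission_counts(200, 500, d = 0.7, r = 0.3, seed = 8)
  sampler <- sum(s) / (200 * 500)
  expect_lt(abs(engine - sampler), 4 * sqrt(0.25 / 1e5 + 0.25 / 1e5))
})

test_that("configuration errors are caught", {
  expect_error(cross_config(infertile_egg_rate = 1.2), "\\[0, 1\\]")
  expect_error(cross_config(n_founders_aus = 5L), "founders")
  expect_error(cross_config(crossover = list(model = "chiasma")), "crossover")
})

test_that("the simulated design matches the configured cohort structure", {
  cfg <- small_cross(seed = 9)
  sim <- simulate_cross(cfg)
  ped <- sim$dataset$individuals
  expect_equal(sum(ped$cohort == "F1"), cfg$n_f1)
  expect_equal(sum(ped$cohort == "F1" & ped$sex == "M"), cfg$f1_males)
  expect_equal(sum(ped$cohort == "BC1"), cfg$n_bc1_eggs)
  expect_equal(sum(ped$cohort == "BC1" & ped$fate == "adult"), cfg$n_bc1_adults)
  expect_equal(sum(ped$cohort == "BC2"), cfg$n_bc2_eggs)
  # infertile eggs carry no genotypes but remain as records
  inf <- ped$individual_id[ped$fate == "infertile_egg"]
  expect_false(any(sim$dataset$genotypes$individual_id %in% inf))
  expect_true(all(is.na(ped$sex[ped$fate == "infertile_egg"])))
  # dataset passes validation (checked inside simulate_cross, assert again)
  expect_silent(validate_dataset(sim$dataset))
})

test_that("infertile egg counts are binomial at the configured rate", {
  cfg <- cross_config(seed = 10, n_bc2_eggs = 1000L, n_bc2_adults = 50L)
  sim <- simulate_cross(cfg, nuisance = FALSE)
  ped <- sim$dataset$individuals
  n_inf <- sum(ped$cohort == "BC2" & ped$fate == "infertile_egg")
  expect_lt(abs(n_inf - 120), 3 * sqrt(1000 * 0.12 * 0.88))
})

test_that("fair meiosis yields binomial per-marker counts and fair sex ratio", {
  # chi-square goodness of fit over 56 markers, 40 seeds: non-significant in
  # the vast majority (the test is exact-binomial calibrated elsewhere)
  rej <- 0L
  for (s in 1:40) {
    cnt <- simulate_transmission_counts(56, 350, d = 0.5, seed = 1000 + s)
    stat <- sum((cnt - 175)^2 / (350 * 0.25))
    if (stats::pchisq(stat, df = 56, lower.tail = FALSE) < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 4)
  # sex ratio among simulated eggs is fair
  sim <- simulate_cross(small_cross(seed = 12))
  ped <- sim$dataset$individuals
  sx <- ped$sex[ped$cohort %in% c("BC1", "BC2") & !is.na(ped$sex)]
  p <- binom_exact_p(sum(sx == "F"), length(sx), 0.5)
  expect_gt(p, 0.001)
})

test_that("pooled k is fair under d = 0.5 and shifted under centromeric drive", {
  sim <- simulate_cross(small_cross(seed = 13, null_allele_rate = 0,
    abnormality_rates = c(tetraploidy = 0, triploidy = 0, haploidy = 0,
                          trisomy = 0, monosomy = 0)))
  ct <- count_transmissions(sim$dataset)
  k <- mean(ct$records$transmitted)
  expect_lt(abs(k - 0.5), 3 * sqrt(0.25 / nrow(ct$records)))
  # strong centromeric female drive shows up at centromeric female markers
  sim2 <- simulate_cross(small_cross(
    seed = 14, null_allele_rate = 0,
    drive = drive_spec("all", "F", "MI_centromere", d = 0.3),
    abnormality_rates = c(tetraploidy = 0, triploidy = 0, haploidy = 0,
                          trisomy = 0, monosomy = 0)))
  ct2 <- count_transmissions(sim2$dataset)
  rec <- ct2$records
  kf_cen <- mean(rec$transmitted[rec$parent_sex == "F" &
                                   rec$position_class == "centromeric"])
  km <- mean(rec$transmitted[rec$parent_sex == "M"])
  expect_lt(kf_cen, 0.4)
  expect_lt(abs(km - 0.5), 0.05)
})

test_that("an inbreeding penalty biases survivor-only counts but not the truth", {
  cfg <- cross_config(seed = 15, inbreeding_penalty = 0.5,
                      null_allele_rate = 0, infertile_egg_rate = 0,
                      n_f1 = 6L, f1_males = 4L, n_bc1_eggs = 80L,
                      n_bc1_adults = 16L, bc1_adult_males = 8L,
                      n_bc1_breeders_m = 6L, n_bc1_breeders_f = 6L,
                      n_bc2_eggs = 400L, n_bc2_adults = 150L,
                      n_founders_aus = 24L,
                      abnormality_rates = c(tetraploidy = 0, triploidy = 0,
                                            haploidy = 0, trisomy = 0,
                                            monosomy = 0))
  sim <- simulate_cross(cfg)
  ct <- count_transmissions(sim$dataset)
  rec <- ct$records
  ped <- sim$dataset$individuals
  adult <- ped$individual_id[ped$fate == "adult"]
  k_all <- mean(rec$transmitted)
  k_surv <- mean(rec$transmitted[rec$offspring_id %in% adult])
  # survivors are depleted of Australian-homozygous offspring
  expect_lt(k_surv, k_all)
  expect_lt(k_surv, 0.5)
  # while the truth-log transmissions (all conceptuses) remain fair
  expect_lt(abs(k_all - 0.5), 3 * sqrt(0.25 / nrow(rec)))
})

test_that("simulated founder sites recover the configured admixed fraction", {
  fs <- simulate_founder_sites(admixed_fraction = 0.0478, seed = 21)
  wins <- scan_windows(fs$sites, fs$chrom_lengths)
  out <- flag_introgressed(wins)
  expect_lt(abs(out$summary$admixed_diploid_fraction - 0.0478), 0.01)
  # recovered windows match the truth flags
  expect_equal(out$windows$introgressed, fs$truth$introgressed_truth)
})
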