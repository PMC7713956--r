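# Founder-admixture screen: count lineage-specific SNPs in fixed windows and
# flag introgressed regions.

#' Count lineage-specific SNPs in non-overlapping windows
#'
#' Tiles each chromosome with half-open windows `[start, start + window)`
#' (0-based coordinates; the last window may be short and is flagged) and
#' counts, per window, the sites that are homozygous non-reference in the
#' focal genome and absent from the reference pool: these are the
#' lineage-specific SNPs whose local depletion marks an introgressed region.
#'
#' @param sites Data frame with columns `chromosome`, `position` (0-based),
#'   `focal_state` (`"hom_nonref"`, `"het"`, `"hom_ref"`) and
#'   `present_in_reference_pool` (logical).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param window Window size in bp (default 500000).
#' @return Data frame with `chromosome`, `start`, `end`, `specific_count`,
#'   `is_short`.
#' @export
scan_windows <- function(sites, chrom_lengths, window = 500000) {
  stopifnot(window > 0)
  bad <- !sites$chromosome %in% names(chrom_lengths)
  if (any(bad)) {
    stop_fmt("coordinate error: sites on unknown chromosome(s): %s",
             paste(unique(sites$chromosome[bad]), collapse = ", "))
  }
  lens <- chrom_lengths[sites$chromosome]
  if (any(sites$position < 0 | sites$position >= lens)) {
    stop_fmt("coordinate error: site position outside chromosome length")
  }
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    sel <- sites$chromosome == ch & sites$focal_state == "hom_nonref" &
      !sites$present_in_reference_pool
    idx <- floor(sites$position[sel] / window) + 1L
    counts <- tabulate(idx, nbins = length(starts))
    out[[ch]] <- data.frame(chromosome = ch, start = starts, end = ends,
                            specific_count = counts,
                            is_short = ends - starts < window,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag introgressed windows and summarize admixed regions
#'
#' A window is introgressed when it carries strictly fewer than `threshold`
#' lineage-specific SNPs. Adjacent introgressed windows are merged into
#' regions, and the admixed fraction of the diploid genome is computed as
#' `sum(region length x weight) / (2 x genome length)` with weight 1 for
#' heterozygous tracts and 2 for homozygous tracts.
#'
#' @param calls Window table from [scan_windows()], optionally with a
#'   `zygosity_note` column (`"heterozygous"`/`"homozygous"`).
#' @param threshold Strict upper bound on specific counts (default 100).
#' @param zygosity Default zygosity for regions lacking a `zygosity_note`
#'   (the study's introgressed regions were all heterozygous).
#' @return List with `windows` (calls plus `introgressed` and
#'   `zygosity_note`), `regions` (merged tracts) and `summary`
#'   (`region_count`, `admixed_diploid_fraction`, `genome_length`).
#' @export
flag_introgressed <- function(calls, threshold = 100,
                              zygosity = "heterozygous") {
  if (threshold <= 0) stop_fmt("threshold must be positive")
  calls$introgressed <- calls$specific_count < threshold
  if (!"zygosity_note" %in% names(calls)) {
    calls$zygosity_note <- ifelse(calls$introgressed, zygosity, NA_character_)
  }
  regions <- list()
  for (ch in unique(calls$chromosome)) {
    w <- calls[calls$chromosome == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    runs <- rle(w$introgressed)
    stops <- cumsum(runs$lengths)
    starts_i <- stops - runs$lengths + 1L
    for (k in which(runs$values)) {
      zy <- unique(stats::na.omit(w$zygosity_note[starts_i[k]:stops[k]]))
      regions[[length(regions) + 1L]] <- data.frame(
        chromosome = ch, start = w$start[starts_i[k]],
        end = w$end[stops[k]], n_windows = runs$lengths[k],
        zygosity = if (length(zy) == 1L) zy else "heterozygous",
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chromosome = character(), start = numeric(), end = numeric(),
               n_windows = integer(), zygosity = character(),
               stringsAsFactors = FALSE)
  genome_length <- sum(calls$end - calls$start)
  weight <- ifelse(regions$zygosity == "homozygous", 2, 1)
  admixed <- if (nrow(regions)) {
    sum((regions$end - regions$start) * weight) / (2 * genome_length)
  } else 0
  list(windows = calls, regions = regions,
       summary = list(region_count = nrow(regions),
                      admixed_diploid_fraction = admixed,
                      genome_length = genome_length))
}

#' Simulate a founder SNP-site table with heterozygous introgressed tracts
#'
#' Emulates the whole-genome comparison of a focal founder against a
#' reference pool: lineage-specific (homozygous non-reference, absent from
#' the pool) SNP counts are high in non-admixed windows and collapse inside
#' heterozygous introgressed tracts. Tracts are placed as runs of whole
#' windows until they cover `2 x admixed_fraction` of the haploid genome, so
#' that the recovered diploid admixed fraction (heterozygous weight 1/2)
#' matches `admixed_fraction`.
#'
#' @param chrom_lengths Named chromosome lengths (default: 10 chromosomes
#'   totalling 200 Mb).
#' @param admixed_fraction Target admixed fraction of the diploid genome
#'   (default 0.0478).
#' @param window Window size (default 500000).
#' @param bg_mean,intro_mean Mean specific-SNP counts per full window outside
#'   and inside tracts (defaults 400 and 20).
#' @param seed Seed.
#' @return List with `sites`, `chrom_lengths`, `truth` (per-window
#'   introgression flags).
#' @export
simulate_founder_sites <- function(chrom_lengths = NULL,
                                   admixed_fraction = 0.0478,
                                   window = 500000,
                                   bg_mean = 400, intro_mean = 20,
                                   seed = 1L) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(
      c(40, 32, 28, 24, 20, 16, 14, 12, 8, 6) * 1e6,
      sprintf("chr%02d", 1:10))
  }
  set.seed(seed)
  wins <- list()
  for (ch in names(chrom_lengths)) {
    starts <- seq(0, chrom_lengths[[ch]] - 1, by = window)
    wins[[ch]] <- data.frame(chromosome = ch, start = starts,
                             end = pmin(starts + window, chrom_lengths[[ch]]),
                             stringsAsFactors = FALSE)
  }
  wins <- do.call(rbind, wins)
  n_win <- nrow(wins)
  target <- round(2 * admixed_fraction * sum(chrom_lengths) / window)
  intro <- rep(FALSE, n_win)
  while (sum(intro) < target) {
    run <- min(1L + stats::rgeom(1, 1 / 3), target - sum(intro))
    at <- sample(n_win, 1)
    span <- at:min(at + run - 1L, n_win)
    span <- span[wins$chromosome[span] == wins$chromosome[at] & !intro[span]]
    intro[span] <- TRUE
  }
  wins$introgressed_truth <- intro
  lens <- wins$end - wins$start
  mean_counts <- ifelse(intro, intro_mean, bg_mean) * lens / window
  counts <- stats::rpois(n_win, mean_counts)
  sites <- do.call(rbind, lapply(which(counts > 0), function(i) {
    data.frame(chromosome = wins$chromosome[i],
               position = wins$start[i] +
                 sort(sample.int(lens[i], counts[i], replace = TRUE)) - 1L,
               focal_state = "hom_nonref",
               present_in_reference_pool = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL
  list(sites = sites, chrom_lengths = chrom_lengths, truth = wins)
}
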