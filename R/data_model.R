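# Domain types: dataset container, validation, TSV readers/writers.

COHORTS <- c("FOUNDER_AUS", "FOUNDER_TIM", "F1", "BC1", "BC2")
FATES <- c("sampled_embryo", "dead_chick", "adult", "infertile_egg", "lost")

# Expected parent cohorts for each offspring cohort (unordered).
COHORT_PARENTS <- list(
  F1  = c("FOUNDER_AUS", "FOUNDER_TIM"),
  BC1 = c("F1", "FOUNDER_AUS"),
  BC2 = c("BC1", "FOUNDER_AUS")
)

#' Construct a pedigree/genotype/marker dataset
#'
#' Bundles the three tables of a backcross experiment into a validated
#' container. `individuals` is the pedigree (one row per bird/embryo/egg),
#' `genotypes` the long-format microsatellite table (one row per individual x
#' marker, with 2-4 allele slots) and `markers` the marker map (chromosome,
#' centromeric/distal class, cM from the centromere, Z linkage).
#'
#' @param individuals Data frame with columns `individual_id`, `sex` (`"F"`,
#'   `"M"` or `NA` for unknown), `dam_id`, `sire_id`, `cohort` (one of
#'   `FOUNDER_AUS`, `FOUNDER_TIM`, `F1`, `BC1`, `BC2`) and `fate` (one of
#'   `sampled_embryo`, `dead_chick`, `adult`, `infertile_egg`, `lost`).
#' @param genotypes Data frame with columns `individual_id`, `marker_id`,
#'   `allele1`, `allele2` and optionally `allele3`, `allele4` (integer
#'   fragment lengths; 0 codes an inferred null allele, -1 the W chromosome).
#' @param markers Data frame with columns `marker_id`, `chromosome`,
#'   `position_class` (`centromeric` or `distal`), `cm_from_centromere` and
#'   `is_z_linked`.
#' @param validate Run [validate_dataset()] (default `TRUE`).
#' @return An object of class `drive_dataset`.
#' @export
new_dataset <- function(individuals, genotypes, markers, validate = TRUE) {
  for (col in c("allele3", "allele4")) {
    if (!col %in% names(genotypes)) {
      genotypes[[col]] <- rep(NA_integer_, nrow(genotypes))
    }
  }
  names(genotypes)[match(c("allele1", "allele2", "allele3", "allele4"),
                         names(genotypes))] <- c("a1", "a2", "a3", "a4")
  for (col in c("a1", "a2", "a3", "a4")) {
    genotypes[[col]] <- as.integer(genotypes[[col]])
  }
  individuals$sex <- as.character(individuals$sex)
  markers$is_z_linked <- as.logical(markers$is_z_linked)
  ds <- structure(list(individuals = individuals,
                       genotypes = genotypes,
                       markers = markers),
                  class = "drive_dataset")
  if (validate) validate_dataset(ds)
  ds
}

#' @export
print.drive_dataset <- function(x, ...) {
  cat(sprintf("<drive_dataset> %d individuals, %d genotypes, %d markers (%d chromosomes)\n",
              nrow(x$individuals), nrow(x$genotypes), nrow(x$markers),
              length(unique(x$markers$chromosome))))
  invisible(x)
}

req_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_fmt("format error in %s: missing column(s) %s", what,
             paste(miss, collapse = ", "))
  }
}

#' Validate a dataset's structural invariants
#'
#' Enforces referential integrity (every genotype references a known
#' individual and marker, every named parent exists and has the right sex),
#' pedigree sanity (cohort transitions follow the breeding design, no
#' individual is its own ancestor, unknown sex only for non-adults), genotype
#' invariants (positive allele lengths, at most one NULL/W placeholder, ZW
#' females hemizygous at Z-linked markers) and marker-map invariants
#' (centromeric markers within 27 cM of the centromere, at most one
#' centromeric and one distal marker per chromosome).
#'
#' @param ds A `drive_dataset`.
#' @return `ds`, invisibly. Errors describe all offending records.
#' @export
validate_dataset <- function(ds) {
  ped <- ds$individuals
  g <- ds$genotypes
  mk <- ds$markers
  req_cols(ped, c("individual_id", "sex", "dam_id", "sire_id", "cohort", "fate"),
           "pedigree")
  req_cols(g, c("individual_id", "marker_id", "a1", "a2"), "genotypes")
  req_cols(mk, c("marker_id", "chromosome", "position_class",
                 "cm_from_centromere", "is_z_linked"), "markers")

  if (anyDuplicated(ped$individual_id)) {
    stop_fmt("duplication error: repeated individual_id in pedigree: %s",
             paste(unique(ped$individual_id[duplicated(ped$individual_id)]),
                   collapse = ", "))
  }
  bad <- !ped$cohort %in% COHORTS
  if (any(bad)) stop_fmt("unknown cohort for: %s",
                         paste(ped$individual_id[bad], collapse = ", "))
  bad <- !ped$fate %in% FATES
  if (any(bad)) stop_fmt("unknown fate for: %s",
                         paste(ped$individual_id[bad], collapse = ", "))
  bad <- !is.na(ped$sex) & !ped$sex %in% c("F", "M")
  if (any(bad)) stop_fmt("sex must be F, M or NA: %s",
                         paste(ped$individual_id[bad], collapse = ", "))
  bad <- is.na(ped$sex) & ped$fate == "adult"
  if (any(bad)) stop_fmt("unknown sex is permitted only for embryos/eggs, not adults: %s",
                         paste(ped$individual_id[bad], collapse = ", "))

  # referential integrity of parents
  for (side in c("dam_id", "sire_id")) {
    pid <- ped[[side]]
    dangling <- !is.na(pid) & !pid %in% ped$individual_id
    if (any(dangling)) {
      stop_fmt("referential error: %s references unknown individual(s): %s",
               side, paste(unique(pid[dangling]), collapse = ", "))
    }
    want <- if (side == "dam_id") "F" else "M"
    psex <- ped$sex[match(pid, ped$individual_id)]
    bad <- !is.na(pid) & (is.na(psex) | psex != want)
    if (any(bad)) {
      stop_fmt("referential error: %s of %s must have sex %s",
               side, paste(ped$individual_id[bad], collapse = ", "), want)
    }
  }

  # cohort consistency with parents' cohorts
  has_par <- !is.na(ped$dam_id) & !is.na(ped$sire_id)
  dc <- ped$cohort[match(ped$dam_id, ped$individual_id)]
  sc <- ped$cohort[match(ped$sire_id, ped$individual_id)]
  for (co in names(COHORT_PARENTS)) {
    rows <- which(ped$cohort == co & has_par)
    want <- COHORT_PARENTS[[co]]
    ok <- (dc[rows] == want[1] & sc[rows] == want[2]) |
      (dc[rows] == want[2] & sc[rows] == want[1])
    if (any(!ok)) {
      stop_fmt("cohort error: %s offspring must have %s x %s parents: %s",
               co, want[1], want[2],
               paste(ped$individual_id[rows][!ok], collapse = ", "))
    }
  }
  rows <- which(ped$cohort %in% c("FOUNDER_AUS", "FOUNDER_TIM") & has_par)
  if (length(rows)) {
    stop_fmt("cohort error: founders cannot have in-pedigree parents: %s",
             paste(ped$individual_id[rows], collapse = ", "))
  }

  # no individual is its own ancestor (walk up the pedigree)
  idx_dam <- match(ped$dam_id, ped$individual_id)
  idx_sire <- match(ped$sire_id, ped$individual_id)
  n <- nrow(ped)
  depth <- rep(NA_integer_, n)
  compute_depth <- function(i, stack) {
    if (!is.na(depth[i])) return(depth[i])
    if (i %in% stack) {
      stop_fmt("pedigree cycle: %s is its own ancestor", ped$individual_id[i])
    }
    stack <- c(stack, i)
    d <- 0L
    for (p in c(idx_dam[i], idx_sire[i])) {
      if (!is.na(p)) d <- max(d, compute_depth(p, stack) + 1L)
    }
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) compute_depth(i, integer())

  # marker map invariants
  if (anyDuplicated(mk$marker_id)) {
    stop_fmt("duplication error: repeated marker_id in map")
  }
  bad <- !mk$position_class %in% c("centromeric", "distal")
  if (any(bad)) stop_fmt("position_class must be centromeric/distal: %s",
                         paste(mk$marker_id[bad], collapse = ", "))
  if (any(mk$cm_from_centromere < 0)) stop_fmt("negative cm_from_centromere")
  bad <- mk$position_class == "centromeric" & mk$cm_from_centromere > 27
  if (any(bad)) stop_fmt("centromeric markers must be <= 27 cM from the centromere: %s",
                         paste(mk$marker_id[bad], collapse = ", "))
  tab <- table(mk$chromosome, mk$position_class)
  if (any(tab > 1)) {
    stop_fmt("at most one centromeric and one distal marker per chromosome")
  }

  # genotype invariants
  if (nrow(g)) {
    bad <- !g$individual_id %in% ped$individual_id
    if (any(bad)) stop_fmt("referential error: genotypes reference unknown individual(s): %s",
                           paste(unique(g$individual_id[bad]), collapse = ", "))
    bad <- !g$marker_id %in% mk$marker_id
    if (any(bad)) stop_fmt("referential error: genotypes reference unknown marker(s): %s",
                           paste(unique(g$marker_id[bad]), collapse = ", "))
    key <- paste(g$individual_id, g$marker_id)
    if (anyDuplicated(key)) {
      stop_fmt("duplication error: repeated (individual, marker) genotype rows: %s",
               paste(unique(key[duplicated(key)]), collapse = "; "))
    }
    if (any(is.na(g$a1)) || any(is.na(g$a2))) {
      stop_fmt("genotypes must carry two allele slots (use NULL/W codes, not NA)")
    }
    slots <- cbind(g$a1, g$a2, g$a3, g$a4)
    bad_code <- rowSums(!is.na(slots) & slots < W_PLACEHOLDER) > 0
    if (any(bad_code)) stop_fmt("allele lengths must be positive integers (or 0/-1 codes)")
    n_placeholder <- rowSums(!is.na(slots) & slots <= 0L)
    if (any(n_placeholder > 1L)) {
      stop_fmt("at most one NULL/W placeholder per genotype: %s",
               paste(unique(g$individual_id[n_placeholder > 1L]), collapse = ", "))
    }
    # ZW female at Z-linked marker: exactly one observable allele (one W slot)
    zm <- mk$marker_id[mk$is_z_linked]
    sexes <- ped$sex[match(g$individual_id, ped$individual_id)]
    zf <- g$marker_id %in% zm & !is.na(sexes) & sexes == "F"
    if (any(zf)) {
      ok <- g$a2[zf] == W_PLACEHOLDER & g$a1[zf] > 0L & is.na(g$a3[zf])
      if (any(!ok)) {
        stop_fmt("ZW females must be hemizygous (allele, W) at Z-linked markers: %s",
                 paste(unique(g$individual_id[zf][!ok]), collapse = ", "))
      }
    }
    bad_w <- rowSums(!is.na(slots) & slots == W_PLACEHOLDER) > 0 &
      !g$marker_id %in% zm
    if (any(bad_w)) {
      stop_fmt("W placeholder used at non-Z-linked marker for: %s",
               paste(unique(g$individual_id[bad_w]), collapse = ", "))
    }
    # non-founders need their parents present (checked above); every genotype of
    # an offspring whose parents are absent would have failed referential checks
  }
  invisible(ds)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, colClasses = NA)
}

#' Read a dataset from its three TSV files
#'
#' Files are tab-separated with header rows and `"NA"` for missing values:
#' `genotypes.tsv` (individual_id, marker_id, allele1, allele2 and optional
#' allele3/allele4 for non-diploid genotypes), `pedigree.tsv` (individual_id,
#' sex, dam_id, sire_id, cohort, fate) and `markers.tsv` (marker_id,
#' chromosome, position_class, cm_from_centromere, is_z_linked).
#'
#' @param genotype_path,pedigree_path,map_path Paths to the three files.
#' @return A validated `drive_dataset`.
#' @export
read_dataset <- function(genotype_path, pedigree_path, map_path) {
  for (p in c(genotype_path, pedigree_path, map_path)) {
    if (!file.exists(p)) stop_fmt("file not found: %s", p)
  }
  g <- read_tsv(genotype_path)
  ped <- read_tsv(pedigree_path)
  mk <- read_tsv(map_path)
  req_cols(g, c("individual_id", "marker_id", "allele1", "allele2"),
           basename(genotype_path))
  req_cols(ped, c("individual_id", "sex", "dam_id", "sire_id", "cohort", "fate"),
           basename(pedigree_path))
  req_cols(mk, c("marker_id", "chromosome", "position_class",
                 "cm_from_centromere", "is_z_linked"), basename(map_path))
  ped$individual_id <- as.character(ped$individual_id)
  ped$dam_id <- as.character(ped$dam_id)
  ped$sire_id <- as.character(ped$sire_id)
  g$individual_id <- as.character(g$individual_id)
  g$marker_id <- as.character(g$marker_id)
  mk$marker_id <- as.character(mk$marker_id)
  mk$chromosome <- as.character(mk$chromosome)
  new_dataset(ped, g, mk)
}

#' Write a dataset to three TSV files
#'
#' Emits `pedigree.tsv`, `genotypes.tsv` and `markers.tsv` in the dialect of
#' [read_dataset()]; the round trip is lossless. The optional `allele3`/
#' `allele4` genotype columns are written only when some genotype uses them.
#'
#' @param ds A `drive_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- ds$genotypes
  names(g)[match(c("a1", "a2", "a3", "a4"), names(g))] <-
    c("allele1", "allele2", "allele3", "allele4")
  if (all(is.na(g$allele3))) g$allele3 <- g$allele4 <- NULL
  paths <- c(
    genotypes = file.path(out_dir, "genotypes.tsv"),
    pedigree = file.path(out_dir, "pedigree.tsv"),
    markers = file.path(out_dir, "markers.tsv")
  )
  utils::write.table(g, paths[["genotypes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(ds$individuals, paths[["pedigree"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(ds$markers, paths[["markers"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(paths)
}
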