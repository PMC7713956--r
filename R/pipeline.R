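# One-command orchestration: simulate (or read) -> validate -> screen ->
# count -> test -> report. Every excluded datum lands in exactly one ledger
# category and all outputs are deterministic given the config seed.

pipeline_log <- function(con, verbose, ...) {
  msg <- sprintf(...)
  if (verbose) message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full distortion-analysis pipeline
#'
#' Stages: build the dataset (from a `simulate:` block via
#' [simulate_cross()], or from `data:` file paths via [read_dataset()]),
#' validate it, screen for chromosomal abnormalities, infer null alleles,
#' build the origin registry, count informative transmissions, estimate the
#' background rate from male parents, test markers and pooled groups against
#' it, fit the random-intercept models (marker- and individual-grouped, and
#' the eight-level generation x position x sex model), run the power
#' analysis and the sex-ratio test, and (optionally) the introgression
#' window scan. Writes `results.tsv`, `transmissions.tsv`, `anomalies.tsv`,
#' `windows.tsv`/`regions.tsv`, `informativeness_ledger.json`,
#' `models.json`, `power.tsv`, `sex_ratio.json`, `manifest.json` and
#' `run.log` into `out_dir`.
#'
#' @param config Path to a YAML config file, or an equivalent nested list.
#'   Recognized blocks: `simulate:` ([cross_config()] fields, with `drive:`
#'   a list of [drive_spec()] rows), or `data:` with `genotypes`,
#'   `pedigree`, `markers` paths; `analysis:` with `p0` (`"auto"` or a
#'   number), `background_method` (`"glmm"`/`"raw"`); `scan:` with `sites`
#'   (TSV path) and `chrom_lengths`, or `simulate: true`.
#' @param out_dir Output directory.
#' @param seed Optional root seed overriding the config seed.
#' @param verbose Log progress to stderr as well as `run.log`.
#' @return Invisibly, a list with the main in-memory results and file paths.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, verbose = TRUE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  log <- function(...) pipeline_log(logcon, verbose, ...)

  truth <- NULL
  sim_cfg <- NULL
  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    if (!is.null(seed)) sc$seed <- seed
    drive <- if (!is.null(sc$drive)) {
      do.call(rbind, lapply(sc$drive, function(d) do.call(drive_spec, d)))
    } else NULL
    sc$drive <- NULL
    sim_cfg <- do.call(cross_config, c(sc, list(drive = drive)))
    log("stage simulate: seed %d", sim_cfg$seed)
    sim <- simulate_cross(sim_cfg)
    ds <- sim$dataset
    truth <- sim$truth
    write_dataset(ds, file.path(out_dir, "dataset"))
  } else if (!is.null(cfg$data)) {
    log("stage read: %s", cfg$data$genotypes)
    ds <- read_dataset(cfg$data$genotypes, cfg$data$pedigree, cfg$data$markers)
  } else {
    stop_fmt("pipeline config error [stage config]: need a 'simulate' or 'data' block")
  }
  log("stage validate: %d individuals, %d genotypes, %d markers",
      nrow(ds$individuals), nrow(ds$genotypes), nrow(ds$markers))
  validate_dataset(ds)

  # anomaly screen --------------------------------------------------------
  calls <- detect_anomalies(ds)
  calls <- classify_mechanism(calls, ds)
  write_tsv(calls, file.path(out_dir, "anomalies.tsv"))
  log("stage screen: %d anomaly calls", nrow(calls))

  # null-allele inference (anomalous offspring excluded) ------------------
  ni <- infer_null_alleles(ds, exclude_individuals = calls$offspring_id)
  ds <- ni$dataset
  log("stage nulls: %d inferred null alleles", nrow(ni$calls))
  qc <- check_mendelian_consistency(ds)
  log("stage qc: %d residual Mendelian flags", nrow(qc))

  # registry + transmission counting --------------------------------------
  registry <- build_origin_registry(ds)
  counted <- count_transmissions(ds, registry, anomaly_calls = calls)
  records <- counted$records
  write_tsv(records, file.path(out_dir, "transmissions.tsv"))
  ledger <- counted$ledger
  log("stage count: %d informative of %d transmissions (%.1f%%)",
      ledger$informative, ledger$total_transmissions,
      ledger$informative_pct)

  an <- cfg$analysis %||% list()
  method <- an$background_method %||% "glmm"
  p0_cfg <- an$p0 %||% "auto"
  p0 <- if (identical(p0_cfg, "auto")) {
    as.numeric(background_rate(records, method = method))
  } else as.numeric(p0_cfg)
  log("stage background: p0 = %.4f (%s)", p0,
      if (identical(p0_cfg, "auto")) method else "configured")

  results <- build_results_table(records, ds, registry, p0)
  write_tsv(results, file.path(out_dir, "results.tsv"))

  models <- fit_models(records, p0, log)
  jsonlite::write_json(models_to_json(models),
                       file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  # power ------------------------------------------------------------------
  pooled <- results[results$scope == "pooled" & results$subset == "all", ]
  power <- do.call(rbind, lapply(seq_len(nrow(pooled)), function(i) {
    ps <- power_detectable_k(pooled$n[i])
    data.frame(group = pooled$group[i], n = ps$n, alpha = ps$alpha,
               target_power = ps$target_power, k_bound = ps$k_bound,
               k_bound_lower = 1 - ps$k_bound, stringsAsFactors = FALSE)
  }))
  write_tsv(power, file.path(out_dir, "power.tsv"))

  # sex ratio ---------------------------------------------------------------
  bc <- ds$individuals[ds$individuals$cohort %in% c("BC1", "BC2"), ]
  sr <- sex_ratio_test(bc$sex)
  jsonlite::write_json(sr, file.path(out_dir, "sex_ratio.json"),
                       auto_unbox = TRUE, digits = NA)
  log("stage sex_ratio: FMR = %.3f (p = %.3g)", sr$fmr, sr$p)

  # multiplicity ledger ------------------------------------------------------
  n_markers <- length(unique(ds$markers$marker_id))
  bonf <- bonferroni_ledger(c(markers = n_markers, generations = 2,
                              sexes = 2, variants = 2))
  ledger_out <- c(unclass(ledger),
                  list(null_calls = nrow(ni$calls),
                       mendelian_flags = nrow(qc),
                       anomaly_calls = nrow(calls),
                       bonferroni = bonf))
  jsonlite::write_json(ledger_out,
                       file.path(out_dir, "informativeness_ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # introgression scan -------------------------------------------------------
  scan_out <- NULL
  if (!is.null(cfg$scan)) {
    if (isTRUE(cfg$scan$simulate)) {
      fs <- simulate_founder_sites(
        admixed_fraction = cfg$scan$admixed_fraction %||%
          (sim_cfg$founder_introgression %||% 0.0478),
        seed = derive_seed(sim_cfg$seed %||% 1L, "sites"))
      sites <- fs$sites
      lens <- fs$chrom_lengths
    } else {
      sites <- read_tsv(cfg$scan$sites)
      lens <- unlist(cfg$scan$chrom_lengths)
    }
    wins <- scan_windows(sites, lens, window = cfg$scan$window %||% 500000)
    scan_out <- flag_introgressed(wins,
                                  threshold = cfg$scan$threshold %||% 100)
    write_tsv(scan_out$windows, file.path(out_dir, "windows.tsv"))
    write_tsv(scan_out$regions, file.path(out_dir, "regions.tsv"))
    log("stage scan: %d introgressed regions, admixed diploid fraction %.4f",
        scan_out$summary$region_count,
        scan_out$summary$admixed_diploid_fraction)
  }

  # manifest ------------------------------------------------------------------
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% c("run.log", "manifest.json")]
  manifest <- list(
    config = cfg,
    seed = sim_cfg$seed %||% NA,
    package_version = as.character(utils::packageVersion("meiodrive")),
    digests = as.list(tools::md5sum(sort(outputs))),
    tests_registry = bonf
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("pipeline complete: %s", out_dir)
  invisible(list(dataset = ds, truth = truth, records = records,
                 results = results, models = models, ledger = ledger_out,
                 p0 = p0, sex_ratio = sr, scan = scan_out,
                 out_dir = out_dir))
}

# One row per scope x subset: per-marker tests in each sex, pooled groups
# and the robustness subsets, all against the supplied background rate.
build_results_table <- function(records, ds, registry, p0) {
  gen_of <- records$parent_cohort
  rows <- list()
  add_row <- function(recs, scope, group, subset, marker = NA_character_) {
    if (!nrow(recs)) return(invisible())
    est <- estimate_k(sum(recs$transmitted), nrow(recs), p0, scope = group)
    rows[[length(rows) + 1L]] <<- data.frame(
      scope = scope, group = group, subset = subset, marker_id = marker,
      n = est$n, successes = est$successes, k = est$k,
      ci_lo = est$ci95[1], ci_hi = est$ci95[2],
      p_binomial = est$p_binomial, p_wald = est$p_wald,
      k_vs_background = est$k_vs_background, p0 = p0,
      stringsAsFactors = FALSE)
  }
  for (sex in c("F", "M")) {
    sx <- records[records$parent_sex == sex, , drop = FALSE]
    for (m in unique(sx$marker_id)) {
      for (gen in unique(sx$parent_cohort[sx$marker_id == m])) {
        add_row(sx[sx$marker_id == m & sx$parent_cohort == gen, , drop = FALSE],
                "marker", paste(m, gen, sex, sep = "."), "all", marker = m)
      }
    }
  }
  add_row(records, "pooled", "all", "all")
  for (sex in c("F", "M")) {
    sx <- records[records$parent_sex == sex, , drop = FALSE]
    add_row(sx, "pooled", paste0("sex.", sex), "all")
    for (pos in c("centromeric", "distal")) {
      sp <- sx[sx$position_class == pos, , drop = FALSE]
      add_row(sp, "pooled", paste("sex", sex, pos, sep = "."), "all")
      for (gen in c("F1", "BC1")) {
        add_row(sp[sp$parent_cohort == gen, , drop = FALSE], "pooled",
                paste(gen, pos, sex, sep = "."), "all")
      }
    }
  }
  for (subset in c("heterozygous_parents", "no_inbreeding")) {
    sub <- subset_transmissions(records, ds, subset, registry = registry)
    add_row(sub, "pooled", "all", subset)
  }
  do.call(rbind, rows)
}

fit_models <- function(records, p0, log) {
  models <- list()
  fem <- records[records$parent_sex == "F", , drop = FALSE]
  try_fit <- function(name, counts, ...) {
    fit <- try(glmm_fit(counts, ...), silent = TRUE)
    if (inherits(fit, "try-error")) {
      log("stage models: %s failed (%s)", name, attr(fit, "condition")$message)
      return(NULL)
    }
    models[[name]] <<- fit
    fit
  }
  if (nrow(fem)) {
    try_fit("female_marker", records_to_counts(fem, "marker"), p0 = p0)
  }
  try_fit("all_marker", records_to_counts(records, "marker"), p0 = p0)
  # eight-level generation x position x sex model (cell means, marker RI)
  counts8 <- records_to_counts(records, "marker", with_level = TRUE)
  fit8 <- try_fit("eight_level", counts8, p0 = p0, fixed = "cell_means")
  if (!is.null(fit8)) {
    focal <- "BC1.centromeric.F"
    if (focal %in% names(fit8$beta)) {
      ctr <- try(contrast_level(fit8, focal, counts8), silent = TRUE)
      if (!inherits(ctr, "try-error")) models$contrast_BC1_cen_F <- ctr
    }
  }
  # among-individual heterogeneity in BC1 females
  bc1f <- records[records$parent_sex == "F" & records$parent_cohort == "BC1", ,
                  drop = FALSE]
  if (length(unique(bc1f$parent_id)) >= 2L) {
    for (pos in c("centromeric", "distal")) {
      sub <- bc1f[bc1f$position_class == pos, , drop = FALSE]
      if (length(unique(sub$parent_id)) < 2L) next
      fit <- try_fit(paste0("bc1_female_individual_", pos),
                     records_to_counts(sub, "individual"), p0 = p0)
      if (!is.null(fit)) {
        glm0 <- glm_offset_fit(sum(sub$transmitted), nrow(sub), p0)
        ll0 <- sum(stats::dbinom(sum(sub$transmitted), nrow(sub),
                                 stats::plogis(stats::qlogis(p0) + glm0$beta0),
                                 log = TRUE))
        # null log-likelihood on the same grouped data
        counts <- records_to_counts(sub, "individual")
        ll0 <- sum(stats::dbinom(counts$successes, counts$n,
                                 stats::plogis(stats::qlogis(p0) + glm0$beta0),
                                 log = TRUE))
        models[[paste0("lrt_individual_", pos)]] <-
          lrt_random_effect(ll0, fit$loglik)
      }
    }
  }
  models
}

models_to_json <- function(models) {
  lapply(models, function(m) {
    if (inherits(m, "glmm_fit")) {
      list(fixed = m$fixed, beta = as.list(m$beta), sigma = m$sigma,
           loglik = m$loglik, k_pop = m$k_pop, p_wald = m$p_wald,
           converged = m$converged, nodes = m$nodes, p0 = m$p0,
           n_groups = m$n_groups, n_obs = m$n_obs)
    } else m
  })
}
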