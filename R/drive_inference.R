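# Drive-parameter estimation and tests: exact binomial tests against a
# background rate, the equivalent offset GLM, power analysis, multiplicity
# accounting and the offspring sex-ratio test.

#' Central two-sided exact binomial p-value (vectorized)
#'
#' Doubles the smaller tail probability and caps at 1, matching the symmetry
#' of the offset-GLM Wald test. The minimum-likelihood definition used by
#' [stats::binom.test()] is available via `method = "minlik"`.
#'
#' @param successes,n Integer vectors.
#' @param p0 Null success probability.
#' @param method `"central"` (default) or `"minlik"`.
#' @return Numeric vector of p-values.
#' @export
binom_exact_p <- function(successes, n, p0 = 0.5,
                          method = c("central", "minlik")) {
  method <- match.arg(method)
  if (method == "minlik") {
    return(mapply(function(s, nn)
      stats::binom.test(s, nn, p = p0)$p.value, successes, n))
  }
  lower <- stats::pbinom(successes, n, p0)
  upper <- stats::pbinom(successes - 1L, n, p0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

# Wilson score interval (vectorized)
wilson_ci <- function(successes, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- successes / n
  den <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  cbind(lower = center - half, upper = center + half)
}

#' Fit the offset binomial GLM in closed form
#'
#' The intercept-only binomial GLM with offset `logit(p0)` has the analytic
#' MLE `beta0 = logit(k) - logit(p0)` with `k = successes/n`; its Wald test
#' is the GLM equivalent of the binomial test against `p0`. At the boundary
#' (`successes` 0 or `n`) the Wald SE is undefined and a profile-likelihood
#' interval is reported instead.
#'
#' @param successes,n Counts.
#' @param p0 Background transmission rate (offset).
#' @return List with `beta0`, `se`, `p_wald`, `k`, `boundary`, and `ci95`
#'   for `beta0` (Wald, or profile at the boundary).
#' @export
glm_offset_fit <- function(successes, n, p0 = 0.5) {
  stopifnot(n >= 1, successes >= 0, successes <= n, p0 > 0, p0 < 1)
  k <- successes / n
  if (successes == 0 || successes == n) {
    # boundary: beta0 -> +-Inf; report profile-likelihood interval for beta0
    ll <- function(b) {
      p <- stats::plogis(stats::qlogis(p0) + b)
      out <- 0
      if (successes > 0) out <- out + successes * log(p)
      if (successes < n) out <- out + (n - successes) * log1p(-p)
      out
    }
    llmax <- if (successes == 0) 0 else 0 # sup of ll as b -> +-Inf is 0
    cut <- llmax - stats::qchisq(0.95, 1) / 2
    if (successes == 0) {
      hi <- stats::uniroot(function(b) ll(b) - cut, c(-50, 50))$root
      ci <- c(-Inf, hi)
      beta0 <- -Inf
    } else {
      lo <- stats::uniroot(function(b) ll(b) - cut, c(-50, 50))$root
      ci <- c(lo, Inf)
      beta0 <- Inf
    }
    return(list(beta0 = beta0, se = NA_real_, p_wald = NA_real_, k = k,
                boundary = TRUE, ci95 = ci))
  }
  beta0 <- stats::qlogis(k) - stats::qlogis(p0)
  se <- 1 / sqrt(n * k * (1 - k))
  list(beta0 = beta0, se = se, p_wald = 2 * stats::pnorm(-abs(beta0) / se),
       k = k, boundary = FALSE,
       ci95 = c(beta0 - stats::qnorm(0.975) * se,
                beta0 + stats::qnorm(0.975) * se))
}

#' Estimate the drive parameter k with exact and Wald tests
#'
#' `k` is the proportion of transmissions carrying the Australian-origin
#' allele; fair Mendelian segregation corresponds to `k = 0.5`, and testing
#' against a background rate `p0` (typically the pooled male estimate)
#' absorbs viability confounds shared by the sexes. Reports the Wilson 95%
#' interval, the central exact binomial p-value against `p0` and the Wald
#' p-value from the equivalent offset GLM, plus the background-relative
#' estimate `invlogit(logit(k) - logit(p0))` (the scale on which 0.5 means
#' "equal to background").
#'
#' @param successes Number of Australian-allele transmissions.
#' @param n Number of informative transmissions.
#' @param p0 Background transmission rate.
#' @param scope Optional label describing what was pooled.
#' @return Object of class `drive_estimate`.
#' @export
estimate_k <- function(successes, n, p0 = 0.5, scope = "pooled") {
  if (n == 0) stop_fmt("undefined estimate: n = 0 informative transmissions")
  stopifnot(successes >= 0, successes <= n, p0 > 0, p0 < 1)
  k <- successes / n
  ci <- wilson_ci(successes, n)
  fit <- glm_offset_fit(successes, n, p0)
  structure(list(
    scope = scope, n = as.integer(n), successes = as.integer(successes),
    k = k, ci95 = c(ci[1, "lower"], ci[1, "upper"]),
    p_binomial = binom_exact_p(successes, n, p0),
    p_wald = fit$p_wald, beta0 = fit$beta0,
    k_vs_background = stats::plogis(fit$beta0),
    p0 = p0
  ), class = "drive_estimate")
}

#' @export
print.drive_estimate <- function(x, ...) {
  cat(sprintf("<drive_estimate> %s: k = %.4f (%d/%d), 95%% CI [%.4f, %.4f]\n",
              x$scope, x$k, x$successes, x$n, x$ci95[1], x$ci95[2]))
  cat(sprintf("  vs background p0 = %.4f: exact p = %.4g, Wald p = %.4g\n",
              x$p0, x$p_binomial, x$p_wald))
  invisible(x)
}

#' Estimate the background transmission rate from male parents
#'
#' The pooled male-parent transmission rate serves as the null probability
#' for all female tests, absorbing transmission biases (genotyping error,
#' viability selection) shared by the sexes. The default estimate is the
#' population-level intercept of a marker-random-intercept GLMM
#' ([glmm_fit()]); `method = "raw"` uses the raw pooled proportion (the two
#' differ only when marker sizes are unbalanced and sigma > 0).
#'
#' @param records Transmission records (see [count_transmissions()]).
#' @param method `"glmm"` or `"raw"`.
#' @return Background rate `p0` (numeric scalar) with attribute `"fit"` for
#'   the GLMM method.
#' @export
background_rate <- function(records, method = c("glmm", "raw")) {
  method <- match.arg(method)
  males <- records[records$parent_sex == "M", , drop = FALSE]
  if (!nrow(males)) {
    stop_fmt("no male-parent records: supply p0 = 0.5 explicitly instead")
  }
  if (method == "raw" || length(unique(males$marker_id)) < 2L) {
    return(sum(males$transmitted) / nrow(males))
  }
  counts <- records_to_counts(males, grouping = "marker")
  fit <- glmm_fit(counts, p0 = 0.5, fixed = "intercept_only")
  structure(fit$k_pop, fit = fit)
}

#' Aggregate transmission records into grouped counts for model fitting
#'
#' @param records Transmission records.
#' @param grouping `"marker"` or `"individual"` (random-intercept grouping).
#' @param with_level Add the `level` factor generation x position x sex
#'   (eight levels in the full design).
#' @return Data frame with `group`, `successes`, `n` (and `level`).
#' @export
records_to_counts <- function(records, grouping = c("marker", "individual"),
                              with_level = FALSE) {
  grouping <- match.arg(grouping)
  gvar <- if (grouping == "marker") records$marker_id else records$parent_id
  by <- list(group = gvar)
  if (with_level) {
    by$level <- paste(records$parent_cohort, records$position_class,
                      records$parent_sex, sep = ".")
  }
  agg <- stats::aggregate(
    cbind(successes = records$transmitted, n = rep(1L, nrow(records))),
    by = by, FUN = sum)
  agg
}

#' Power analysis for detecting deviations from a 0.5 transmission ratio
#'
#' Uses the arcsine-transform normal approximation for a one-sample
#' proportion test (effect size `h = 2 asin(sqrt(k)) - 2 asin(sqrt(0.5))`,
#' power `= Phi(h sqrt(n) - z[1-alpha/2]) + Phi(-h sqrt(n) - z[1-alpha/2])`).
#' `power_detectable_k()` solves for the smallest detectable `k > 0.5` at a
#' given `n`; `required_n()` inverts for the sample size. Effects are
#' symmetric: `k` and `1 - k` are equivalent. `power_exact_binom()` computes
#' the exact power of the central exact binomial test by enumeration.
#'
#' @param n Number of informative transmissions.
#' @param alpha Two-sided significance level.
#' @param target_power Desired power.
#' @return `power_detectable_k()`: list of class `power_spec` with `n`,
#'   `alpha`, `target_power`, `k_bound` (`> 0.5`; `1 - k_bound` is the
#'   symmetric lower bound) and `power_exact` (exact-binomial power at
#'   `k_bound`, for cross-checking the approximation).
#' @export
power_detectable_k <- function(n, alpha = 0.05, target_power = 0.8) {
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  if (target_power <= alpha) {
    stop_fmt("infeasible: target power (%.3f) must exceed alpha (%.3f)",
             target_power, alpha)
  }
  f <- function(k) power_arcsine(k, n, alpha) - target_power
  k_bound <- stats::uniroot(f, c(0.5 + 1e-12, 1 - 1e-12), tol = 1e-12)$root
  structure(list(n = n, alpha = alpha, target_power = target_power,
                 k_bound = k_bound,
                 power_exact = power_exact_binom(k_bound, n, alpha),
                 note = "k and 1-k are equivalent (symmetric two-sided test)"),
            class = "power_spec")
}

#' @rdname power_detectable_k
#' @param k Alternative transmission probability (`k != 0.5`).
#' @export
required_n <- function(k, alpha = 0.05, target_power = 0.8) {
  stopifnot(k > 0, k < 1, alpha > 0, alpha < 1)
  if (abs(k - 0.5) < 1e-12) {
    stop_fmt("infeasible: k = 0.5 is the null; no sample size detects a zero effect")
  }
  if (target_power <= alpha) {
    stop_fmt("infeasible: target power must exceed alpha")
  }
  h <- abs(2 * asin(sqrt(k)) - 2 * asin(sqrt(0.5)))
  n0 <- ((stats::qnorm(1 - alpha / 2) + stats::qnorm(target_power)) / h)^2
  # refine on the exact arcsine power (the second tail adds a little power)
  while (power_arcsine(k, ceiling(n0), alpha) < target_power) n0 <- n0 * 1.01
  as.integer(ceiling(n0))
}

#' @rdname power_detectable_k
#' @export
power_arcsine <- function(k, n, alpha = 0.05) {
  h <- 2 * asin(sqrt(k)) - 2 * asin(sqrt(0.5))
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(h * sqrt(n) - z) + stats::pnorm(-h * sqrt(n) - z)
}

#' @rdname power_detectable_k
#' @param p0 Null probability of the exact test.
#' @export
power_exact_binom <- function(k, n, alpha = 0.05, p0 = 0.5) {
  s <- 0:n
  pvals <- binom_exact_p(s, n, p0)
  sum(stats::dbinom(s[pvals <= alpha], n, k))
}

#' Multiple-testing ledger with Bonferroni arithmetic
#'
#' Enumerates the tests actually run by the pipeline (marker x generation x
#' sex x analysis variant) and reports the Bonferroni-corrected p-values.
#' Nominal p-values remain the default throughout the package; the ledger is
#' the on-demand accounting of what a family-wise correction would imply.
#'
#' @param test_registry Either a data frame with one row per test (columns
#'   identifying the dimensions, optionally `p`), or a named integer vector
#'   of dimension sizes (e.g. `c(markers = 56, generations = 2, sexes = 2,
#'   variants = 2)`).
#' @param p Optional nominal p-value(s) to correct.
#' @return List with `m` (number of tests), `alpha_corrected`
#'   (`0.05 / m`) and, when `p` is given, `p_corrected = pmin(1, m * p)`.
#' @export
bonferroni_ledger <- function(test_registry, p = NULL) {
  if (is.data.frame(test_registry)) {
    m <- nrow(test_registry)
    if (is.null(p) && "p" %in% names(test_registry)) p <- test_registry$p
  } else {
    m <- prod(as.numeric(test_registry))
  }
  out <- list(m = as.integer(m), alpha_corrected = 0.05 / m)
  if (!is.null(p)) out$p_corrected <- pmin(1, m * p)
  out
}

#' Offspring sex-ratio test
#'
#' Computes the female-male ratio (FMR) with a delta-method interval on the
#' log scale and an exact binomial test of the proportion of females against
#' 0.5. Reports both the conventional +-1 SE interval and the 95% CI. With
#' zero counts of one sex the interval falls back to the exact
#' Clopper-Pearson interval transformed to the FMR scale.
#'
#' @param sexes Character vector of offspring sexes (`"F"`/`"M"`, `NA`
#'   ignored), or `NULL` if `n_female`/`n_male` are given.
#' @param n_female,n_male Counts (alternative input).
#' @return List with `fmr`, `se_interval` (+-1 SE on log FMR), `ci95`, `p`
#'   and the counts.
#' @export
sex_ratio_test <- function(sexes = NULL, n_female = NULL, n_male = NULL) {
  if (!is.null(sexes)) {
    n_female <- sum(sexes == "F", na.rm = TRUE)
    n_male <- sum(sexes == "M", na.rm = TRUE)
  }
  ntot <- n_female + n_male
  if (ntot == 0) stop_fmt("no sexed offspring")
  p <- binom_exact_p(n_female, ntot, 0.5)
  if (n_female == 0 || n_male == 0) {
    cp <- stats::binom.test(n_female, ntot)$conf.int
    ci <- cp / (1 - cp)
    fmr <- n_female / max(n_male, 1)
    return(list(fmr = fmr, se_interval = c(NA_real_, NA_real_),
                ci95 = ci, p = p, n_female = n_female, n_male = n_male,
                note = "exact CI fallback (zero count in one sex)"))
  }
  fmr <- n_female / n_male
  se_log <- sqrt(1 / n_female + 1 / n_male)
  list(fmr = fmr,
       se_interval = exp(log(fmr) + c(-1, 1) * se_log),
       ci95 = exp(log(fmr) + c(-1, 1) * stats::qnorm(0.975) * se_log),
       p = p, n_female = n_female, n_male = n_male)
}
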