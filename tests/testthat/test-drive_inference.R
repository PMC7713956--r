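# k estimation, offset GLM, background rate, GLMM quadrature, LRT, contrast,
# power analysis, multiplicity ledger and sex-ratio test.

test_that("estimate_k reproduces the printed ABxAB tally and symmetries", {
  est <- estimate_k(164, 330, p0 = 0.5)
  expect_equal(round(est$k, 4), 0.497)
  expect_true(est$ci95[1] <= est$k && est$k <= est$ci95[2])
  # successes = n/2 at p0 = 0.5: exact central p is 1
  expect_equal(estimate_k(165, 330, 0.5)$p_binomial, 1)
  # independent tail-sum oracle for 45/100 vs 0.5
  p_oracle <- 2 * sum(stats::dbinom(0:45, 100, 0.5))
  expect_equal(estimate_k(45, 100, 0.5)$p_binomial, p_oracle, tolerance = 1e-12)
  expect_equal(round(p_oracle, 3), 0.368)
  expect_error(estimate_k(0, 0), "n = 0")
})

test_that("offset GLM has the analytic MLE and matches numeric optimization", {
  f <- glm_offset_fit(489, 1000, p0 = 0.495)
  expect_equal(f$beta0, stats::qlogis(0.489) - stats::qlogis(0.495),
               tolerance = 1e-12)
  expect_equal(round(f$beta0, 4), -0.024)
  expect_equal(glm_offset_fit(495, 1000, 0.495)$beta0, 0, tolerance = 1e-12)
  # numeric-optimizer oracle over a grid
  for (case in list(c(7, 20, 0.4), c(123, 400, 0.52), c(1, 10, 0.5),
                    c(350, 700, 0.495))) {
    s <- case[1]; n <- case[2]; p0 <- case[3]
    score <- function(b) s - n * stats::plogis(stats::qlogis(p0) + b)
    num <- stats::uniroot(score, c(-10, 10), tol = 1e-14)$root
    expect_lt(abs(glm_offset_fit(s, n, p0)$beta0 - num), 1e-8)
  }
  # boundary cases report profile intervals, not Wald
  b0 <- glm_offset_fit(0, 25, 0.5)
  expect_true(b0$boundary)
  expect_true(is.finite(b0$ci95[2]) && !is.finite(b0$ci95[1]))
  bn <- glm_offset_fit(25, 25, 0.5)
  expect_true(is.finite(bn$ci95[1]) && !is.finite(bn$ci95[2]))
})

test_that("background rate: raw pooling, GLMM mode and their divergence", {
  rec <- data.frame(parent_id = "p", parent_sex = "M", parent_cohort = "F1",
                    offspring_id = "o", marker_id = rep(c("m1", "m2"), c(1000, 1000)),
                    chromosome = "c", position_class = "centromeric",
                    transmitted = rep(c(1L, 0L), c(990, 1010)),
                    stringsAsFactors = FALSE)
  expect_equal(as.numeric(background_rate(rec, method = "raw")), 0.495)
  expect_error(background_rate(rec[rec$parent_sex == "F", , drop = FALSE]),
               "0.5")
  # balanced, homogeneous markers: GLMM equals raw
  set.seed(31)
  recs <- data.frame(parent_id = "p", parent_sex = "M", parent_cohort = "F1",
                     offspring_id = "o",
                     marker_id = rep(paste0("m", 1:8), each = 250),
                     chromosome = "c", position_class = "centromeric",
                     transmitted = rep(rep(c(1L, 0L), c(130, 120)), 8),
                     stringsAsFactors = FALSE)
  expect_equal(as.numeric(background_rate(recs, "glmm")),
               as.numeric(background_rate(recs, "raw")), tolerance = 1e-5)
  # unbalanced sizes + real heterogeneity: the two differ
  set.seed(32)
  ns <- c(2000, 50, 50, 50, 50, 50)
  ps <- stats::plogis(stats::qlogis(0.5) + c(0.6, -0.4, -0.5, -0.3, -0.45, -0.5))
  recs2 <- do.call(rbind, lapply(seq_along(ns), function(i) {
    data.frame(parent_id = "p", parent_sex = "M", parent_cohort = "F1",
               offspring_id = "o", marker_id = paste0("m", i),
               chromosome = "c", position_class = "centromeric",
               transmitted = stats::rbinom(ns[i], 1, ps[i]),
               stringsAsFactors = FALSE)
  }))
  expect_gt(abs(as.numeric(background_rate(recs2, "glmm")) -
                  as.numeric(background_rate(recs2, "raw"))), 0.005)
})

test_that("GLMM quadrature equals brute-force integration and the GLM limit", {
  counts <- data.frame(group = c("a", "b", "c"), successes = c(8, 5, 2),
                       n = c(10, 10, 10))
  fit <- glmm_fit(counts, p0 = 0.5)
  expect_lt(abs(fit$loglik -
                  oracle_glmm_ll(fit$beta[1], fit$sigma, counts, 0.5)), 1e-6)
  # identical proportions: sigma -> 0 and beta matches the offset GLM
  c2 <- data.frame(group = c("a", "b", "c"), successes = c(6, 6, 6),
                   n = c(10, 10, 10))
  f2 <- glmm_fit(c2, p0 = 0.5)
  expect_lt(f2$sigma, 1e-4)
  expect_lt(abs(f2$beta[1] - glm_offset_fit(18, 30, 0.5)$beta0), 1e-6)
  expect_error(glmm_fit(c2[1, ]), ">= 2 groups")
})

test_that("GLMM fit matches an independent mixed-model implementation", {
  set.seed(30)
  u <- stats::rnorm(30, 0, 0.3)
  counts <- data.frame(group = paste0("g", 1:30),
                       successes = stats::rbinom(30, 300,
                                                 stats::plogis(0.2 + u)),
                       n = 300)
  fit <- glmm_fit(counts, p0 = 0.5)
  m <- lme4::glmer(cbind(successes, n - successes) ~ 1 + (1 | group),
                   data = counts, family = stats::binomial, nAGQ = 20)
  expect_equal(unname(fit$beta[1]), unname(lme4::fixef(m)), tolerance = 1e-3)
  expect_equal(fit$sigma, sqrt(unlist(lme4::VarCorr(m))[[1]]),
               tolerance = 1e-3)
})

test_that("GLMM recovers a known random-intercept SD", {
  sigmas <- numeric(20)
  set.seed(33)
  for (r in seq_len(20)) {
    u <- stats::rnorm(56, 0, 0.3)
    counts <- data.frame(group = paste0("g", 1:56),
                         successes = stats::rbinom(56, 350, stats::plogis(u)),
                         n = 350)
    sigmas[r] <- glmm_fit(counts, p0 = 0.5)$sigma
  }
  expect_lt(abs(stats::median(sigmas) - 0.3), 0.1)
})

test_that("random-effect LRT: identities and boundary conservatism", {
  out <- lrt_random_effect(0, 0)
  expect_equal(out$lr, 0)
  expect_equal(out$p_nominal, 1)
  out2 <- lrt_random_effect(0, 1.92)
  expect_equal(out2$lr, 3.84)
  expect_equal(out2$p_nominal, 0.05, tolerance = 0.001)
  expect_equal(out2$p_boundary, 0.025, tolerance = 0.001)
  expect_error(lrt_random_effect(10, 9.5), "optimization failure")
  # homogeneous groups: nominal LRT rejects at most ~5% (conservative)
  set.seed(34)
  rej <- 0L
  for (r in 1:100) {
    counts <- data.frame(group = paste0("g", 1:6),
                         successes = stats::rbinom(6, 60, 0.5), n = 60)
    f1 <- glmm_fit(counts, p0 = 0.5, nodes = 10)
    ll0 <- sum(stats::dbinom(counts$successes, counts$n,
                             sum(counts$successes) / sum(counts$n),
                             log = TRUE))
    lr <- lrt_random_effect(ll0, f1$loglik)
    if (lr$p_nominal < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 8)
})

test_that("cell-means contrast behaves and matches hand-built algebra", {
  set.seed(35)
  lev <- rep(c("A", "B", "C", "D"), each = 14)
  counts <- data.frame(group = paste0("m", 1:56),
                       level = lev,
                       successes = stats::rbinom(56, 350, 0.5), n = 350)
  fit <- glmm_fit(counts, p0 = 0.5, fixed = "cell_means")
  ctr <- contrast_level(fit, "A", counts)
  expect_gt(ctr$p, 0.05)
  # hand-built linear combination on the same fit
  w <- tapply(counts$n, counts$level, sum)[c("B", "C", "D")]
  w <- w / sum(w)
  cvec <- c(1, -w)
  est <- sum(cvec * fit$beta[c("A", "B", "C", "D")])
  v <- drop(t(cvec) %*% fit$vcov[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
            %*% cvec)
  expect_equal(ctr$estimate, est, tolerance = 1e-10)
  expect_equal(ctr$se, sqrt(v), tolerance = 1e-10)
  # a strongly displaced level is detected
  counts2 <- counts
  counts2$successes[counts2$level == "A"] <- stats::rbinom(14, 350, 0.65)
  fit2 <- glmm_fit(counts2, p0 = 0.5, fixed = "cell_means")
  expect_lt(contrast_level(fit2, "A", counts2)$p, 0.001)
  expect_error(contrast_level(fit2, "Z", counts2), "missing level")
})

test_that("power analysis: closed form, exact cross-check, monotonicity", {
  ps <- power_detectable_k(9469, alpha = 0.05, target_power = 0.8)
  expect_equal(ps$k_bound, 0.51439, tolerance = 5e-4)
  expect_equal(ps$power_exact, 0.8, tolerance = 0.02)
  # strictly decreasing in n
  ks <- vapply(c(500, 2000, 9469, 40000), function(n)
    power_detectable_k(n)$k_bound, numeric(1))
  expect_true(all(diff(ks) < 0))
  # inverse round trip
  n_back <- required_n(ps$k_bound, 0.05, 0.8)
  expect_lt(abs(n_back - 9469) / 9469, 0.02)
  expect_error(required_n(0.5), "infeasible")
  expect_error(power_detectable_k(100, alpha = 0.05, target_power = 0.04),
               "infeasible")
})

test_that("multiplicity ledger arithmetic", {
  b <- bonferroni_ledger(c(markers = 56, generations = 2, sexes = 2,
                           variants = 2), p = 6e-5)
  expect_equal(b$m, 448L)
  expect_equal(round(b$p_corrected, 2), 0.03)
  expect_equal(bonferroni_ledger(c(1), p = 0.02)$p_corrected, 0.02)
  reg <- expand.grid(marker = paste0("m", 1:3), sex = c("F", "M"))
  reg$p <- 0.4
  b2 <- bonferroni_ledger(reg)
  expect_equal(b2$m, 6L)
  expect_equal(b2$p_corrected, rep(1, 6))
})

test_that("sex-ratio test: arithmetic, equality and interval coverage", {
  sr <- sex_ratio_test(n_female = 107, n_male = 100)
  expect_equal(sr$fmr, 1.07)
  sr2 <- sex_ratio_test(n_female = 50, n_male = 50)
  expect_equal(sr2$fmr, 1)
  expect_equal(sr2$p, 1)
  sr3 <- sex_ratio_test(n_female = 0, n_male = 20)
  expect_true(is.finite(sr3$ci95[2]))
  # 95% CI coverage under a fair ratio, n = 1348
  set.seed(36)
  cover <- 0L
  for (r in 1:400) {
    nf <- stats::rbinom(1, 1348, 0.5)
    ci <- sex_ratio_test(n_female = nf, n_male = 1348 - nf)$ci95
    if (ci[1] <= 1 && 1 <= ci[2]) cover <- cover + 1L
  }
  expect_gt(cover / 400, 0.92)
  expect_lt(cover / 400, 0.985)
})
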