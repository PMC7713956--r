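# Binomial random-intercept models with a fixed offset, fitted by maximizing
# the logit-normal marginal likelihood via adaptive Gauss-Hermite quadrature.
# This is the model used for background-rate estimation, pooled drive tests
# and the among-individual heterogeneity LRT.

#' Gauss-Hermite nodes and weights
#'
#' Computes the nodes and weights of the n-point Gauss-Hermite rule (weight
#' function `exp(-x^2)`) from the eigendecomposition of the Jacobi matrix
#' (Golub-Welsch).
#'
#' @param n Number of nodes.
#' @return List with numeric vectors `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

# log binomial likelihood contribution of rows with linear predictor eta
binom_ll_rows <- function(y, n, eta) {
  stats::dbinom(y, n, stats::plogis(eta), log = TRUE)
}

# Marginal log-likelihood of one group via adaptive GH quadrature.
# y, n, eta0 are the group's rows (eta0 = fixed part incl. offset).
group_marginal_ll <- function(y, n, eta0, sigma, gh) {
  if (sigma < 1e-8) return(sum(binom_ll_rows(y, n, eta0)))
  # Newton search for the mode of h(u) = loglik(u) + log dnorm(u; 0, sigma)
  u <- 0
  for (it in 1:50) {
    p <- stats::plogis(eta0 + u)
    g1 <- sum(y - n * p) - u / sigma^2
    g2 <- -sum(n * p * (1 - p)) - 1 / sigma^2
    step <- g1 / g2
    u <- u - step
    if (abs(step) < 1e-10) break
  }
  p <- stats::plogis(eta0 + u)
  s <- 1 / sqrt(sum(n * p * (1 - p)) + 1 / sigma^2)
  uk <- u + sqrt(2) * s * gh$nodes
  hk <- vapply(uk, function(ui) {
    sum(binom_ll_rows(y, n, eta0 + ui)) +
      stats::dnorm(ui, 0, sigma, log = TRUE)
  }, numeric(1))
  log(sqrt(2) * s) + logsumexp(log(gh$weights) + gh$nodes^2 + hk)
}

# Full marginal log-likelihood over all groups.
glmm_marginal_ll <- function(beta, sigma, X, y, n, group, offset, gh) {
  eta0 <- drop(X %*% beta) + offset
  ll <- 0
  for (ids in split(seq_along(y), group)) {
    ll <- ll + group_marginal_ll(y[ids], n[ids], eta0[ids], sigma, gh)
  }
  ll
}

#' Fit a binomial random-intercept model with an offset
#'
#' Maximizes the marginal likelihood of the model
#' `logit P(success) = offset + X beta + u_g`, `u_g ~ N(0, sigma^2)`,
#' with `offset = logit(p0)` (the background transmission rate), by adaptive
#' Gauss-Hermite quadrature. Fixed effects are either an intercept only or a
#' cell-means parameterization of a grouping factor (e.g. the eight levels of
#' generation x chromosomal position x parent sex).
#'
#' @param counts Data frame with columns `group` (random-intercept grouping:
#'   marker or individual identity), `successes`, `n`, and optionally `level`
#'   (factor for the cell-means fixed effect).
#' @param p0 Background transmission rate entering as the offset
#'   (`logit(p0)`); `0.5` yields a zero offset.
#' @param fixed `"intercept_only"` or `"cell_means"` (one coefficient per
#'   `level`, no global intercept).
#' @param nodes Number of quadrature nodes (default 20).
#' @return An object of class `glmm_fit`: `beta` (logit scale, relative to
#'   the offset), `sigma`, `loglik`, `vcov` (of `beta`), `k_pop` (for
#'   intercept models, the population-level `invlogit(offset + beta0)` at
#'   `u = 0`; conditional and marginal scales differ when `sigma > 0`),
#'   `p_wald` (intercept models), `converged`, `nodes`, `p0`.
#' @export
glmm_fit <- function(counts, p0 = 0.5, fixed = c("intercept_only", "cell_means"),
                     nodes = 20L) {
  fixed <- match.arg(fixed)
  stopifnot(all(c("group", "successes", "n") %in% names(counts)))
  if (length(unique(counts$group)) < 2L) {
    stop_fmt("glmm_fit needs >= 2 groups; got %d",
             length(unique(counts$group)))
  }
  y <- as.numeric(counts$successes)
  n <- as.numeric(counts$n)
  group <- as.factor(counts$group)
  if (fixed == "cell_means") {
    if (!"level" %in% names(counts)) {
      stop_fmt("fixed = 'cell_means' requires a 'level' column")
    }
    lev <- factor(counts$level)
    X <- stats::model.matrix(~ 0 + lev)
    colnames(X) <- levels(lev)
    empty <- setdiff(levels(lev), unique(as.character(lev)))
    if (length(empty)) stop_fmt("empty level cells: %s",
                                paste(empty, collapse = ", "))
  } else {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }
  offset <- rep(stats::qlogis(p0), length(y))
  gh <- gauss_hermite(nodes)
  p <- ncol(X)
  negll <- function(theta) {
    -glmm_marginal_ll(theta[seq_len(p)], theta[p + 1L], X, y, n, group,
                      offset, gh)
  }
  # start: per-cell empirical logits relative to offset
  start_beta <- vapply(seq_len(p), function(j) {
    rows <- X[, j] > 0
    stats::qlogis((sum(y[rows]) + 0.5) / (sum(n[rows]) + 1)) - stats::qlogis(p0)
  }, numeric(1))
  opt <- stats::optim(c(start_beta, 0.3), negll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, p), 0),
                      upper = c(rep(Inf, p), Inf),
                      control = list(maxit = 500))
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  sigma <- opt$par[p + 1L]
  vc <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  hess_ok <- TRUE
  H <- try(stats::optimHess(opt$par, negll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    Hb <- H[seq_len(p), seq_len(p), drop = FALSE]
    vb <- try(solve(Hb), silent = TRUE)
    if (!inherits(vb, "try-error")) {
      dimnames(vb) <- list(colnames(X), colnames(X))
      vc <- vb
    } else {
      hess_ok <- FALSE
    }
  } else {
    hess_ok <- FALSE
  }
  k_pop <- NA_real_
  p_wald <- NA_real_
  if (fixed == "intercept_only") {
    k_pop <- stats::plogis(stats::qlogis(p0) + beta[1])
    if (is.finite(vc[1, 1]) && vc[1, 1] > 0) {
      p_wald <- 2 * stats::pnorm(-abs(beta[1]) / sqrt(vc[1, 1]))
    }
  }
  structure(list(beta = beta, sigma = sigma, loglik = -opt$value,
                 vcov = vc, k_pop = unname(k_pop), p_wald = unname(p_wald),
                 converged = (opt$convergence == 0) && hess_ok,
                 nodes = nodes, p0 = p0, fixed = fixed,
                 n_groups = length(unique(group)),
                 n_obs = sum(n)),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %s, %d groups, %d transmissions\n", x$fixed,
              x$n_groups, x$n_obs))
  cat("  beta:", paste(sprintf("%s=%.4f", names(x$beta), x$beta),
                       collapse = ", "), "\n")
  cat(sprintf("  sigma = %.4f, loglik = %.3f, p0 = %.4f\n",
              x$sigma, x$loglik, x$p0))
  if (!is.na(x$k_pop)) cat(sprintf("  population k = %.4f (Wald p = %.3g)\n",
                                   x$k_pop, x$p_wald))
  invisible(x)
}

#' Likelihood-ratio test for a random-intercept variance
#'
#' Compares the offset GLM (sigma = 0) with the random-intercept GLMM on the
#' same data. Reports the nominal chi-square(1) p-value (the convention of
#' common GLMM software) alongside the boundary-corrected p-value from the
#' 50:50 mixture of chi-square(0) and chi-square(1), which accounts for the
#' null value sigma = 0 lying on the parameter boundary.
#'
#' @param loglik_null Log-likelihood of the sigma = 0 (offset GLM) fit, or an
#'   object with a `loglik` field.
#' @param loglik_alt Log-likelihood of the GLMM fit, or a `glmm_fit`.
#' @param tol Tolerance for a slightly negative LR due to optimizer noise.
#' @return List with `lr`, `p_nominal`, `p_boundary`.
#' @export
lrt_random_effect <- function(loglik_null, loglik_alt, tol = 1e-6) {
  ll0 <- if (is.list(loglik_null)) loglik_null$loglik else loglik_null
  ll1 <- if (is.list(loglik_alt)) loglik_alt$loglik else loglik_alt
  lr <- 2 * (ll1 - ll0)
  if (lr < -tol) {
    stop_fmt("optimization failure: GLMM log-likelihood below nested GLM by %g",
             -lr / 2)
  }
  lr <- max(lr, 0)
  p_nom <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  p_bound <- if (lr == 0) 1 else 0.5 * p_nom
  list(lr = lr, p_nominal = p_nom, p_boundary = p_bound)
}

#' Wald contrast of one cell against the weighted mean of the others
#'
#' Tests whether the focal level's coefficient in a cell-means fit differs
#' from the transmission-weighted mean of the remaining levels' coefficients
#' (weights proportional to each level's number of transmissions).
#'
#' @param fit A `glmm_fit` with `fixed = "cell_means"`.
#' @param focal_level Name of the focal level.
#' @param counts The counts data frame used for the fit (for the weights).
#' @return List with `estimate` (contrast on the logit scale), `se`, `z`,
#'   `p`, and the weight vector used.
#' @export
contrast_level <- function(fit, focal_level, counts) {
  stopifnot(inherits(fit, "glmm_fit"), fit$fixed == "cell_means")
  levs <- names(fit$beta)
  if (!focal_level %in% levs) {
    stop_fmt("missing level '%s'; available: %s", focal_level,
             paste(levs, collapse = ", "))
  }
  n_by_level <- tapply(counts$n, factor(counts$level, levels = levs), sum)
  n_by_level[is.na(n_by_level)] <- 0
  others <- setdiff(levs, focal_level)
  w <- n_by_level[others] / sum(n_by_level[others])
  cvec <- stats::setNames(numeric(length(levs)), levs)
  cvec[focal_level] <- 1
  cvec[others] <- -w
  est <- sum(cvec * fit$beta)
  v <- drop(t(cvec) %*% fit$vcov %*% cvec)
  if (!is.finite(v) || v <= 0) stop_fmt("contrast variance unavailable (fit not converged?)")
  z <- est / sqrt(v)
  list(estimate = est, se = sqrt(v), z = z,
       p = 2 * stats::pnorm(-abs(z)), weights = w)
}
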