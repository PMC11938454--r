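#' Li-Ji effective number of independent tests
#'
#' Computes the effective number of independent tests from the eigenvalues of
#' the correlation matrix among the test variables:
#' `m_eff = sum( I(|lambda_i| >= 1) + (|lambda_i| - floor(|lambda_i|)) )`.
#' Perfectly correlated variables contribute a single effective test;
#' uncorrelated variables contribute one each.
#'
#' @param corr_matrix Symmetric correlation matrix with unit diagonal.
#' @return List with `m_total` (matrix dimension), `m_eff` and `eigenvalues`.
#' @export
li_ji_meff <- function(corr_matrix) {
  M <- as.matrix(corr_matrix)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8)
    stop_validation("correlation matrix must be symmetric")
  if (max(abs(diag(M) - 1)) > 1e-8)
    stop_validation("correlation matrix must have unit diagonal")
  lambda <- abs(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  m_eff <- sum(as.numeric(lambda >= 1) + (lambda - floor(lambda)))
  list(m_total = nrow(M), m_eff = m_eff, eigenvalues = lambda)
}

#' FDR thresholds over the effective number of tests
#'
#' Benjamini-Hochberg step-up in which the effective number of independent
#' tests replaces the raw test count: p-values are sorted ascending, the
#' threshold at rank i is `i * q / m_eff`, and all tests up to the largest
#' rank whose p-value clears its threshold are rejected. Each test's own
#' rank-threshold is reported as the adjusted alpha it was compared against.
#' `method = "bonferroni"` instead applies the single threshold `q / m_eff`
#' to every test.
#'
#' @param p_values Numeric vector in \[0, 1\] (`NA` allowed; never rejected,
#'   threshold `NA`).
#' @param m_eff Effective number of tests (>= 1).
#' @param q FDR level (default 0.05).
#' @param method `"bh"` (step-up, default) or `"bonferroni"`.
#' @return List with `threshold` (per-test adjusted alpha, original order)
#'   and `significant` (logical).
#' @export
adjusted_thresholds <- function(p_values, m_eff, q = 0.05,
                                method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  check_scalar_number(m_eff, "m_eff", 1)
  check_scalar_number(q, "q", 0, 1, open_lower = TRUE, open_upper = TRUE)
  m <- length(p_values)
  if (m == 0L) return(list(threshold = numeric(0), significant = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_validation("p-values outside [0, 1]")
  threshold <- rep(NA_real_, m)
  significant <- rep(FALSE, m)
  obs <- which(!is.na(p_values))
  if (method == "bonferroni") {
    threshold[obs] <- q / m_eff
    significant[obs] <- p_values[obs] < q / m_eff
    return(list(threshold = threshold, significant = significant))
  }
  ord <- obs[order(p_values[obs])]
  ranks <- seq_along(ord)
  thr <- ranks * q / m_eff
  pass <- p_values[ord] <= thr
  cutoff <- if (any(pass)) max(which(pass)) else 0L
  threshold[ord] <- thr
  if (cutoff > 0L) significant[ord[seq_len(cutoff)]] <- TRUE
  list(threshold = threshold, significant = significant)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard BH adjustment (via [stats::p.adjust()]) plus rejection flags at
#' level `q`.
#'
#' @param p_values Numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = !is.na(adj) & adj <= q)
}

#' Standard error from a confidence-interval width
#'
#' Recovers the standard error of a normally distributed estimate from its
#' two-sided confidence interval: `se = (hi - lo) / (2 * z)` with `z` the
#' standard-normal quantile at `(1 + level) / 2`. Used to turn bootstrap
#' percentile intervals into the SEs that inverse-variance meta-analysis
#' weighting needs.
#'
#' @param ci_low,ci_high Interval bounds, `ci_low < ci_high` (equality gives
#'   se 0 with a warning, which breaks downstream weighting).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Standard error (vectorised).
#' @export
se_from_ci <- function(ci_low, ci_high, level = 0.95) {
  check_scalar_number(level, "level", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (any(ci_low > ci_high)) stop_validation("ci_low must be <= ci_high")
  if (any(ci_low == ci_high))
    warning("degenerate CI of width 0: se = 0 breaks inverse-variance weighting")
  (ci_high - ci_low) / (2 * stats::qnorm((1 + level) / 2))
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Pools per-cohort estimates with weights `1 / se^2`:
#' `pooled = sum(e_i / se_i^2) / sum(1 / se_i^2)`,
#' `se = sqrt(1 / sum(1 / se_i^2))`, two-sided normal p. A single cohort is
#' passed through with a warning.
#'
#' @param estimates Numeric vector of cohort estimates.
#' @param ses Matching standard errors (> 0).
#' @return List with `estimate`, `se`, `z`, `p`, `k`.
#' @export
ivw_meta <- function(estimates, ses) {
  if (length(estimates) != length(ses))
    stop_validation("estimates and ses differ in length")
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop_validation("ses must be finite and > 0")
  if (length(estimates) < 2L)
    warning("single-cohort meta-analysis: passing the estimate through")
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- est / se
  list(estimate = est, se = se, z = z,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       k = length(estimates))
}

#' Pool two cohorts' mediation grids
#'
#' Matches the rows of two mediation grids (same variant and measure), turns
#' each model's bootstrap percentile interval into a standard error via
#' [se_from_ci()], and pools the indirect effects by fixed-effect
#' inverse-variance meta-analysis.
#'
#' @param grid1,grid2 `mediation_grid` data.frames from [run_grid()].
#' @param level Confidence level of the bootstrap intervals (default 0.95).
#' @return data.frame with per-model cohort estimates and the pooled
#'   `estimate`, `se`, `p`.
#' @export
meta_mediation <- function(grid1, grid2, level = 0.95) {
  key1 <- paste(grid1$variant_id, grid1$region, grid1$measure_type)
  key2 <- paste(grid2$variant_id, grid2$region, grid2$measure_type)
  shared <- intersect(key1, key2)
  rows <- lapply(shared, function(k) {
    r1 <- grid1[key1 == k, ][1, ]
    r2 <- grid2[key2 == k, ][1, ]
    if (anyNA(c(r1$acme, r1$ci_low, r1$ci_high, r2$acme, r2$ci_low, r2$ci_high)))
      return(NULL)
    se1 <- se_from_ci(r1$ci_low, r1$ci_high, level)
    se2 <- se_from_ci(r2$ci_low, r2$ci_high, level)
    if (se1 == 0 || se2 == 0) return(NULL)
    pooled <- ivw_meta(c(r1$acme, r2$acme), c(se1, se2))
    data.frame(variant_id = r1$variant_id, region = r1$region,
               measure_type = r1$measure_type,
               acme_1 = r1$acme, se_1 = se1, acme_2 = r2$acme, se_2 = se2,
               estimate = pooled$estimate, se = pooled$se, p = pooled$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  out
}

#' Type-I error simulation harness
#'
#' The family-history proxy score is bounded and far from Gaussian, so the
#' validity of testing it with linear regression is checked by simulation:
#' under a generator with zero genotype effect, the path-c (total effect)
#' test should reject at the nominal rate. Each replicate draws a null
#' dataset, regresses the outcome on dosage (plus any covariate columns the
#' generator provides), and records whether the dosage p-value falls below
#' `alpha`.
#'
#' @param null_generator Function of a single integer seed returning a
#'   data.frame with columns `outcome`, `dosage`, and optionally covariates
#'   (every remaining column enters the model).
#' @param n_reps Number of replicates (>= 1000 for a stable rate).
#' @param alpha Nominal test level.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param conf Confidence level of the binomial interval on the rejection
#'   rate.
#' @return List with `rejection_rate`, `ci_low`, `ci_high` (exact binomial),
#'   `n_reps`, `alpha`.
#' @export
type1_sim <- function(null_generator, n_reps = 5000, alpha = 0.05, seed = 1L,
                      conf = 0.99) {
  check_scalar_number(n_reps, "n_reps", 1)
  check_scalar_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  reject <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    d <- null_generator(seed + r)
    covs <- setdiff(names(d), c("outcome", "dosage"))
    X <- design_matrix(d, c("dosage", covs), site = FALSE)
    fit <- ls_fit(X, d$outcome)
    tval <- fit$coef[["dosage"]] / fit$se[["dosage"]]
    p <- 2 * stats::pt(abs(tval), fit$df, lower.tail = FALSE)
    reject[r] <- p < alpha
  }
  ci <- stats::binom.test(sum(reject), n_reps, conf.level = conf)$conf.int
  list(rejection_rate = mean(reject), ci_low = ci[1], ci_high = ci[2],
       n_reps = n_reps, alpha = alpha)
}

#' Null proxy-score data generator
#'
#' Builds a `type1_sim`-compatible generator: each replicate draws a small
#' cohort with one Hardy-Weinberg variant that has no effect on anything and
#' a family-history proxy-score outcome (hence bounded, zero-inflated and
#' right-skewed), plus age and sex covariates.
#'
#' @param n Participants per replicate.
#' @param allele_frequency Variant allele frequency.
#' @return Function of a seed returning a data.frame with `outcome`,
#'   `dosage`, `age`, `sex`.
#' @export
null_proxy_generator <- function(n = 500, allele_frequency = 0.3) {
  force(n); force(allele_frequency)
  function(seed) {
    cfg <- cohort_config(n, seed = seed, cohort_style = "proxy")
    set.seed(seed)
    dosage <- stats::rbinom(n, 2L, allele_frequency)
    covariates <- data.frame(age = rnorm_trunc(n, cfg$age_mean, cfg$age_sd, 40, 100),
                             sex = as.integer(stats::runif(n) < cfg$sex_ratio))
    G <- matrix(dosage, ncol = 1, dimnames = list(NULL, "null_snp"))
    med <- data.frame(row.names = seq_len(n))
    parents <- generate_outcome(G, med, covariates,
                                list(variant_spec("null_snp", "C",
                                                  allele_frequency)),
                                cfg)
    score <- proxy_score(cbind(parents$parent1_affected, parents$parent2_affected),
                         cbind(parents$parent1_age, parents$parent2_age),
                         cbind(parents$parent1_available, parents$parent2_available))
    data.frame(outcome = score, dosage = dosage,
               age = covariates$age, sex = covariates$sex)
  }
}
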