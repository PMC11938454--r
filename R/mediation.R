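#' Specification of one mediation model
#'
#' One cell of the variant-by-measure mediation grid: which variant dosage is
#' the exposure, which standardized regional measure is the mediator, the
#' outcome family, and the bootstrap settings. Covariates are fixed by
#' design: age, sex, assessment site when the cohort has more than one, and
#' the global brain measure matched to the mediator's type (total surface
#' area for areas, global mean thickness for thicknesses, ICV for volumes).
#'
#' @param variant_id Dosage column name in the analysis table.
#' @param region,measure_type Mediator identity; the analysis column is
#'   `<region>__<measure_type>`.
#' @param outcome_family `"linear"` (proxy score) or `"logistic"`
#'   (case/control status).
#' @param bootstrap_reps Number of bootstrap resamples (>= 200).
#' @param seed Integer seed for the bootstrap stream.
#' @return Object of class `mediation_spec`.
#' @export
mediation_spec <- function(variant_id, region, measure_type,
                           outcome_family = c("linear", "logistic"),
                           bootstrap_reps = 5000, seed = 1L) {
  outcome_family <- match.arg(outcome_family)
  measure_type <- match.arg(measure_type, c("area", "thickness", "volume"))
  check_scalar_number(bootstrap_reps, "bootstrap_reps", 200)
  structure(list(variant_id = variant_id, region = region,
                 measure_type = measure_type,
                 measure = paste0(region, "__", measure_type),
                 global_covariate = global_covariate_for(measure_type),
                 outcome_family = outcome_family,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed)),
            class = "mediation_spec")
}

## Shared design construction: one listwise-deletion pass over every column
## any of the three path models needs, so the decomposition c = c' + a*b
## holds on a common sample.
mediation_design <- function(data, spec) {
  covs <- c("age", "sex", spec$global_covariate)
  needed <- c(spec$variant_id, spec$measure, "outcome", covs)
  ok <- complete_rows(data, needed)
  d <- data[ok, , drop = FALSE]
  X_a <- design_matrix(d, c(spec$variant_id, covs))
  p <- ncol(X_a)
  if (nrow(d) < p + 10L)
    stop_validation("only %d complete observations for %d parameters (need >= %d)",
                    nrow(d), p, p + 10L)
  X_y <- design_matrix(d, c(spec$variant_id, spec$measure, covs))
  list(X_a = X_a, y_m = d[[spec$measure]],
       X_y = X_y, y = d$outcome,
       n = nrow(d))
}

#' Fit the mediator model (path a)
#'
#' Least-squares regression of the standardized regional measure on the
#' variant dosage plus the design covariates; the dosage coefficient is
#' path a.
#'
#' @param data Analysis table from [derive_analysis_data()].
#' @param spec A [mediation_spec()].
#' @return List with `estimate`, `se`, `p` (two-sided t), `n`.
#' @export
fit_path_a <- function(data, spec) {
  dz <- mediation_design(data, spec)
  fit <- ls_fit(dz$X_a, dz$y_m)
  est <- fit$coef[[spec$variant_id]]
  se <- fit$se[[spec$variant_id]]
  tval <- est / se
  list(estimate = est, se = se,
       p = 2 * stats::pt(abs(tval), fit$df, lower.tail = FALSE), n = dz$n)
}

#' Fit the outcome model (paths b and c-prime)
#'
#' Regression of the outcome on dosage, mediator and covariates; the mediator
#' coefficient is path b, the dosage coefficient the direct effect c-prime.
#' Linear outcomes use least squares, binary outcomes a logistic model.
#' Non-convergence or separation is returned as an error state, not thrown.
#'
#' @inheritParams fit_path_a
#' @return List with `b`, `se_b`, `p_b`, `c_prime`, `se_c_prime`, `n`,
#'   `error` (`NA_character_` when clean).
#' @export
fit_outcome <- function(data, spec) {
  dz <- mediation_design(data, spec)
  if (spec$outcome_family == "linear") {
    fit <- ls_fit(dz$X_y, dz$y)
    tb <- fit$coef[[spec$measure]] / fit$se[[spec$measure]]
    return(list(b = fit$coef[[spec$measure]], se_b = fit$se[[spec$measure]],
                p_b = 2 * stats::pt(abs(tb), fit$df, lower.tail = FALSE),
                c_prime = fit$coef[[spec$variant_id]],
                se_c_prime = fit$se[[spec$variant_id]],
                n = dz$n, error = NA_character_))
  }
  if (stats::var(dz$y) == 0)
    return(list(b = NA_real_, se_b = NA_real_, p_b = NA_real_,
                c_prime = NA_real_, se_c_prime = NA_real_, n = dz$n,
                error = "degenerate outcome: all cases or all controls"))
  fit <- logit_fit(dz$X_y, dz$y)
  if (!fit$converged)
    return(list(b = NA_real_, se_b = NA_real_, p_b = NA_real_,
                c_prime = NA_real_, se_c_prime = NA_real_, n = dz$n,
                error = "logistic model failed to converge (possible separation)"))
  b <- fit$coef[[spec$measure]]; se_b <- fit$se[[spec$measure]]
  list(b = b, se_b = se_b,
       p_b = 2 * stats::pnorm(abs(b / se_b), lower.tail = FALSE),
       c_prime = fit$coef[[spec$variant_id]],
       se_c_prime = fit$se[[spec$variant_id]],
       n = dz$n, error = NA_character_)
}

#' Fit the total-effect model (path c)
#'
#' Regression of the outcome on dosage and covariates, without the mediator.
#'
#' @inheritParams fit_path_a
#' @return List with `estimate`, `se`, `p`, `n`, `error`.
#' @export
fit_total <- function(data, spec) {
  dz <- mediation_design(data, spec)
  X_c <- dz$X_a  # same columns as the mediator design: dosage + covariates
  if (spec$outcome_family == "linear") {
    fit <- ls_fit(X_c, dz$y)
    est <- fit$coef[[spec$variant_id]]; se <- fit$se[[spec$variant_id]]
    return(list(estimate = est, se = se,
                p = 2 * stats::pt(abs(est / se), fit$df, lower.tail = FALSE),
                n = dz$n, error = NA_character_))
  }
  if (stats::var(dz$y) == 0)
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_, n = dz$n,
                error = "degenerate outcome: all cases or all controls"))
  fit <- logit_fit(X_c, dz$y)
  if (!fit$converged)
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_, n = dz$n,
                error = "logistic model failed to converge (possible separation)"))
  est <- fit$coef[[spec$variant_id]]; se <- fit$se[[spec$variant_id]]
  list(estimate = est, se = se,
       p = 2 * stats::pnorm(abs(est / se), lower.tail = FALSE),
       n = dz$n, error = NA_character_)
}

## ACME on the risk-difference scale by g-computation for a logistic outcome:
## average predicted-probability change when the mediator moves from its
## model-implied value at the observed dosage to its value at dosage + 1,
## with the direct path held at the observed dosage.
acme_gcomp <- function(coef_a, coef_y, X_a, X_y, measure_col) {
  a <- coef_a[[2L]]  # dosage is always the second column of X_a
  mhat <- as.numeric(X_a %*% coef_a)
  X0 <- X_y; X0[, measure_col] <- mhat
  eta0 <- as.numeric(X0 %*% coef_y)
  X0[, measure_col] <- mhat + a
  eta1 <- as.numeric(X0 %*% coef_y)
  mean(stats::plogis(eta1) - stats::plogis(eta0))
}

#' Bootstrap the indirect (mediation) effect
#'
#' Fits the mediator and outcome models, forms the indirect effect -- the
#' product of paths a and b for a linear outcome, or the average causal
#' mediation effect on the risk-difference scale via g-computation for a
#' logistic outcome -- and assesses it by a nonparametric bootstrap over
#' participants: percentile 95% confidence interval and a two-sided bootstrap
#' p-value `2 * min(P(draw <= 0), P(draw >= 0))`.
#'
#' @inheritParams fit_path_a
#' @return Object of class `mediation_result`: a list with the path
#'   estimates (`a`, `se_a`, `p_a`, `b`, `se_b`, `c`, `se_c`, `p_c`,
#'   `c_prime`, `se_c_prime`), `acme`, `ci_low`, `ci_high`, `p_boot`,
#'   `n_used`, `boot_failed` (fraction of non-converged resamples) and
#'   `error`.
#' @export
bootstrap_acme <- function(data, spec) {
  pa <- fit_path_a(data, spec)
  po <- fit_outcome(data, spec)
  pc <- fit_total(data, spec)
  res <- list(spec = spec,
              a = pa$estimate, se_a = pa$se, p_a = pa$p,
              b = po$b, se_b = po$se_b,
              c = pc$estimate, se_c = pc$se, p_c = pc$p,
              c_prime = po$c_prime, se_c_prime = po$se_c_prime,
              acme = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              p_boot = NA_real_, n_used = pa$n, boot_failed = NA_real_,
              error = NA_character_)
  class(res) <- "mediation_result"
  if (!is.na(po$error)) { res$error <- po$error; return(res) }

  dz <- mediation_design(data, spec)
  linear <- spec$outcome_family == "linear"
  measure_col <- which(colnames(dz$X_y) == spec$measure)
  point_coef_a <- ls_fit(dz$X_a, dz$y_m, se = FALSE)$coef
  if (linear) {
    point_coef_y <- ls_fit(dz$X_y, dz$y, se = FALSE)$coef
    res$acme <- point_coef_a[[2L]] * point_coef_y[[measure_col]]
  } else {
    fy <- logit_fit(dz$X_y, dz$y, se = FALSE)
    res$acme <- acme_gcomp(point_coef_a, fy$coef, dz$X_a, dz$X_y, measure_col)
  }

  set.seed(spec$seed)
  B <- spec$bootstrap_reps
  n <- dz$n
  draws <- rep(NA_real_, B)
  for (r in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xa <- dz$X_a[idx, , drop = FALSE]
    Xy <- dz$X_y[idx, , drop = FALSE]
    ca <- tryCatch(qr.coef(qr(Xa), dz$y_m[idx]), error = function(e) NULL)
    if (is.null(ca) || anyNA(ca)) next
    if (linear) {
      cy <- tryCatch(qr.coef(qr(Xy), dz$y[idx]), error = function(e) NULL)
      if (is.null(cy) || anyNA(cy)) next
      draws[r] <- ca[[2L]] * cy[[measure_col]]
    } else {
      fy <- tryCatch(logit_fit(Xy, dz$y[idx], se = FALSE),
                     error = function(e) NULL)
      if (is.null(fy) || !fy$converged) next
      draws[r] <- acme_gcomp(ca, fy$coef, Xa, Xy, measure_col)
    }
  }
  fail <- mean(is.na(draws))
  res$boot_failed <- fail
  if (fail > 0.20) {
    res$error <- sprintf("%.0f%% of bootstrap resamples failed to converge",
                         100 * fail)
    return(res)
  }
  ok <- draws[!is.na(draws)]
  ci <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
  res$ci_low <- ci[1]; res$ci_high <- ci[2]
  res$p_boot <- min(1, 2 * min(mean(ok <= 0), mean(ok >= 0)))
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> outcome (%s)\n",
              x$spec$variant_id, x$spec$measure, x$spec$outcome_family))
  if (!is.na(x$error)) cat("  error state:", x$error, "\n")
  cat(sprintf("  a = %.4f (se %.4f, p %.3g)   b = %.4f (se %.4f)\n",
              x$a, x$se_a, x$p_a, x$b, x$se_b))
  cat(sprintf("  c = %.4f   c' = %.4f\n", x$c, x$c_prime))
  cat(sprintf("  ACME = %.4f  [%.4f, %.4f]  p_boot = %.3g  (n = %d)\n",
              x$acme, x$ci_low, x$ci_high, x$p_boot, x$n_used))
  invisible(x)
}

#' Run the full variant-by-measure mediation grid
#'
#' Fits one mediation model per panel variant and catalog measure, in fixed
#' panel-by-catalog order, with per-model listwise deletion (participants
#' missing that variant's dosage or that measure drop out of that model
#' only). Significance is assessed by Benjamini-Hochberg step-up over the
#' Li-Ji effective number of independent tests, computed from the
#' correlation structure of the measures and dosages on the analysis sample.
#'
#' @param data Analysis table from [derive_analysis_data()].
#' @param variant_ids Character vector of dosage columns (panel order).
#' @param measures Measure catalog rows (catalog order), as from
#'   [measure_catalog()].
#' @param outcome_family `"linear"` or `"logistic"`; default taken from the
#'   table's `outcome_family` attribute.
#' @param bootstrap_reps Bootstrap resamples per model.
#' @param seed Base seed; model `i` uses `seed + i`.
#' @param q FDR level (default 0.05).
#' @param meff_method Passed to [adjusted_thresholds()]: `"bh"` (step-up,
#'   default) or `"bonferroni"` over the effective test count.
#' @return data.frame of class `mediation_grid`, one row per model, with the
#'   path estimates, bootstrap ACME and CI, `p_boot`, per-test `threshold`,
#'   `significant`, `n_used` and `error`; the Li-Ji decomposition is attached
#'   as attribute `m_eff`.
#' @export
run_grid <- function(data, variant_ids, measures = measure_catalog(),
                     outcome_family = NULL, bootstrap_reps = 5000,
                     seed = 1L, q = 0.05, meff_method = c("bh", "bonferroni")) {
  meff_method <- match.arg(meff_method)
  if (is.null(outcome_family))
    outcome_family <- attr(data, "outcome_family") %||% "linear"
  rows <- vector("list", length(variant_ids) * nrow(measures))
  i <- 0L
  for (v in variant_ids) {
    for (k in seq_len(nrow(measures))) {
      i <- i + 1L
      spec <- mediation_spec(v, measures$region[k], measures$measure_type[k],
                             outcome_family, bootstrap_reps,
                             seed = seed + i)
      res <- tryCatch(bootstrap_acme(data, spec), error = function(e)
        list(a = NA_real_, se_a = NA_real_, p_a = NA_real_, b = NA_real_,
             se_b = NA_real_, c = NA_real_, se_c = NA_real_, p_c = NA_real_,
             c_prime = NA_real_, se_c_prime = NA_real_, acme = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, p_boot = NA_real_,
             n_used = NA_integer_, boot_failed = NA_real_,
             error = conditionMessage(e)))
      rows[[i]] <- data.frame(
        variant_id = v, region = measures$region[k],
        measure_type = measures$measure_type[k],
        n_used = res$n_used,
        a = res$a, se_a = res$se_a, p_a = res$p_a,
        b = res$b, se_b = res$se_b,
        c = res$c, se_c = res$se_c, p_c = res$p_c,
        c_prime = res$c_prime, se_c_prime = res$se_c_prime,
        acme = res$acme, ci_low = res$ci_low, ci_high = res$ci_high,
        p_boot = res$p_boot, error = res$error,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)

  ## Li-Ji effective test count: measures and variants are each correlated,
  ## so the effective grid size is the product of the two effective counts.
  meff_m <- li_ji_meff(safe_cor(data[, measures$name, drop = FALSE]))
  meff_v <- li_ji_meff(safe_cor(data[, variant_ids, drop = FALSE]))
  m_eff <- meff_m$m_eff * meff_v$m_eff
  thr <- adjusted_thresholds(out$p_boot, m_eff, q = q, method = meff_method)
  out$threshold <- thr$threshold
  out$significant <- thr$significant
  attr(out, "m_eff") <- list(measures = meff_m$m_eff, variants = meff_v$m_eff,
                             total = m_eff)
  attr(out, "outcome_family") <- outcome_family
  class(out) <- c("mediation_grid", "data.frame")
  out
}

## Pairwise-complete correlation matrix with unit diagonal, robust to
## zero-variance columns (mapped to zero correlation).
safe_cor <- function(df) {
  M <- as.matrix(df)
  C <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}
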