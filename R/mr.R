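#' Instrument set for Mendelian randomization
#'
#' Per-variant association estimates of the instruments with the exposure and
#' with the outcome, as used by every MR estimator in the package.
#'
#' @param variant_id Character vector of instrument ids.
#' @param beta_exposure,se_exposure Per-variant exposure associations and
#'   standard errors.
#' @param beta_outcome,se_outcome Per-variant outcome associations and
#'   standard errors.
#' @return Object of class `instrument_set` with `k` instruments.
#' @export
instrument_set <- function(variant_id, beta_exposure, se_exposure,
                           beta_outcome, se_outcome) {
  k <- length(variant_id)
  if (k < 1L) stop_validation("instrument set needs k >= 1 variants")
  lens <- c(length(beta_exposure), length(se_exposure),
            length(beta_outcome), length(se_outcome))
  if (any(lens != k)) stop_validation("instrument fields differ in length")
  if (any(!is.finite(beta_exposure)) || any(!is.finite(beta_outcome)))
    stop_validation("non-finite instrument associations")
  if (any(!is.finite(se_exposure)) || any(se_exposure <= 0) ||
      any(!is.finite(se_outcome)) || any(se_outcome <= 0))
    stop_validation("instrument SEs must be finite and > 0")
  structure(list(variant_id = as.character(variant_id),
                 beta_exposure = as.numeric(beta_exposure),
                 se_exposure = as.numeric(se_exposure),
                 beta_outcome = as.numeric(beta_outcome),
                 se_outcome = as.numeric(se_outcome),
                 k = k),
            class = "instrument_set")
}

## Orientation normalization: flip (beta_X, beta_Y) jointly so beta_X >= 0.
## Required for MR-Egger; harmless elsewhere.
orient_instruments <- function(ins) {
  flip <- ins$beta_exposure < 0
  ins$beta_exposure[flip] <- -ins$beta_exposure[flip]
  ins$beta_outcome[flip] <- -ins$beta_outcome[flip]
  ins
}

mr_estimate <- function(method, theta, se, p, intercept = NULL,
                        se_intercept = NULL, p_intercept = NULL) {
  structure(list(method = method, theta = theta, se = se, p = p,
                 intercept = intercept, se_intercept = se_intercept,
                 p_intercept = p_intercept),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: theta = %.4f (se %.4f, p %.3g)\n",
              x$method, x$theta, x$se, x$p))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4f (se %.4f, p %.3g)\n",
                x$intercept, x$se_intercept, x$p_intercept))
  invisible(x)
}

#' Inverse-variance-weighted MR estimator
#'
#' Weighted regression of the variant-outcome associations on the
#' variant-exposure associations through the origin, with weights
#' `1 / se_outcome^2`:
#' `theta = sum(bX * bY / seY^2) / sum(bX^2 / seY^2)`, fixed-effect
#' `se = sqrt(1 / sum(bX^2 / seY^2))`, normal-theory two-sided p. With a
#' single instrument this reduces to the Wald ratio `bY / bX`.
#'
#' @param instruments An [instrument_set()].
#' @return An `mr_estimate` with `method = "IVW"`.
#' @export
ivw <- function(instruments) {
  w <- instruments$beta_exposure^2 / instruments$se_outcome^2
  theta <- sum(instruments$beta_exposure * instruments$beta_outcome /
                 instruments$se_outcome^2) / sum(w)
  se <- sqrt(1 / sum(w))
  mr_estimate("IVW", theta, se,
              2 * stats::pnorm(abs(theta / se), lower.tail = FALSE))
}

#' Weighted-median MR estimator
#'
#' Sorts the variant-specific Wald ratios `bY/bX` and takes the value at
#' which the cumulative standardized inverse-variance weight crosses one
#' half, interpolating linearly between adjacent ratios (standardized
#' cumulative weight `s_j = sum_{i<=j} w_i - w_j / 2`). Consistent when at
#' least half the total weight comes from valid instruments. The standard
#' error is estimated by a parametric bootstrap, resampling each instrument's
#' associations from normal distributions with the supplied SEs.
#'
#' @param instruments An [instrument_set()] with k >= 3.
#' @param n_boot Parametric bootstrap draws for the SE (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_estimate` with `method = "weighted_median"`.
#' @export
weighted_median <- function(instruments, n_boot = 200, seed = 1L) {
  if (instruments$k < 3L)
    stop_validation("weighted median requires k >= 3 instruments")
  ins <- orient_instruments(instruments)
  theta <- weighted_median_point(ins$beta_exposure, ins$beta_outcome,
                                 ins$se_outcome)
  set.seed(seed)
  boot <- replicate(n_boot, {
    bx <- stats::rnorm(ins$k, ins$beta_exposure, ins$se_exposure)
    by <- stats::rnorm(ins$k, ins$beta_outcome, ins$se_outcome)
    weighted_median_point(bx, by, ins$se_outcome)
  })
  se <- stats::sd(boot)
  p <- if (se > 0) 2 * stats::pnorm(abs(theta / se), lower.tail = FALSE)
       else as.numeric(theta == 0)
  mr_estimate("weighted_median", theta, se, p)
}

## Point estimate: interpolated weighted median of the Wald ratios.
weighted_median_point <- function(bx, by, sey) {
  ratio <- by / bx
  w <- bx^2 / sey^2
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(ratio[1])
  k <- length(ratio)
  if (s[k] <= 0.5) return(ratio[k])
  j <- max(which(s < 0.5))
  ratio[j] + (ratio[j + 1] - ratio[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' MR-Egger regression
#'
#' Weighted linear regression of the variant-outcome associations on the
#' variant-exposure associations with a free intercept, weights
#' `1 / se_outcome^2`, after orienting each instrument so its exposure
#' association is non-negative. The slope is the causal estimate; the
#' intercept estimates directional horizontal pleiotropy and its test is the
#' Egger intercept test.
#'
#' @param instruments An [instrument_set()] with k >= 3 and non-constant
#'   exposure associations.
#' @return An `mr_estimate` with `method = "MR_Egger"`, including
#'   `intercept`, `se_intercept`, `p_intercept`.
#' @export
mr_egger <- function(instruments) {
  if (instruments$k < 3L)
    stop_validation("MR-Egger requires k >= 3 instruments")
  ins <- orient_instruments(instruments)
  if (stats::var(ins$beta_exposure) == 0)
    stop_validation("MR-Egger slope unidentifiable: all exposure associations equal")
  w <- 1 / ins$se_outcome^2
  sw <- sqrt(w)
  X <- cbind(intercept = sw, slope = sw * ins$beta_exposure)
  fit <- ls_fit(X, sw * ins$beta_outcome)
  theta <- fit$coef[["slope"]]; se_t <- fit$se[["slope"]]
  b0 <- fit$coef[["intercept"]]; se_0 <- fit$se[["intercept"]]
  mr_estimate("MR_Egger", theta, se_t,
              2 * stats::pnorm(abs(theta / se_t), lower.tail = FALSE),
              intercept = b0, se_intercept = se_0,
              p_intercept = 2 * stats::pnorm(abs(b0 / se_0), lower.tail = FALSE))
}

#' Cochran's Q heterogeneity statistic
#'
#' Weighted squared deviation of the variant-specific Wald ratios from the
#' IVW estimate, `Q = sum w_j (ratio_j - theta_IVW)^2` with
#' `w_j = bX_j^2 / seY_j^2`; chi-square with k-1 degrees of freedom under
#' homogeneity.
#'
#' @param instruments An [instrument_set()] with k >= 2.
#' @return List with `q`, `df`, `p`.
#' @export
cochran_q <- function(instruments) {
  if (instruments$k < 2L) stop_validation("Cochran's Q requires k >= 2")
  theta <- ivw(instruments)$theta
  ratio <- instruments$beta_outcome / instruments$beta_exposure
  w <- instruments$beta_exposure^2 / instruments$se_outcome^2
  q <- sum(w * (ratio - theta)^2)
  df <- instruments$k - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Instrument-strength statistic for MR-Egger
#'
#' `I2_GX = max(0, (Q_GX - (k-1)) / Q_GX)` where `Q_GX` is the heterogeneity
#' of the exposure associations about their inverse-variance-weighted mean,
#' `Q_GX = sum (bX_j - mean_w)^2 / seX_j^2`. Values below 0.8 indicate the
#' MR-Egger slope is unreliable (regression dilution) and raise the flag.
#'
#' @param instruments An [instrument_set()] with k >= 2 and exposure SEs.
#' @return List with `i2_gx`, `q_gx` and `weak_flag` (`i2_gx < 0.80`).
#' @export
i2_gx <- function(instruments) {
  if (instruments$k < 2L) stop_validation("I2_GX requires k >= 2")
  ins <- orient_instruments(instruments)
  w <- 1 / ins$se_exposure^2
  mw <- sum(w * ins$beta_exposure) / sum(w)
  q_gx <- sum((ins$beta_exposure - mw)^2 / ins$se_exposure^2)
  i2 <- if (q_gx > 0) max(0, (q_gx - (ins$k - 1)) / q_gx) else 0
  list(i2_gx = i2, q_gx = q_gx, weak_flag = i2 < 0.80)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect k times, dropping each instrument in turn, to
#' expose estimates driven by a single variant. With k = 2 each re-estimate
#' is a single-instrument Wald ratio and is flagged as such.
#'
#' @param instruments An [instrument_set()] with k >= 2.
#' @param level Confidence level for the reported intervals.
#' @return data.frame with one row per dropped variant: `dropped`, `theta`,
#'   `se`, `ci_low`, `ci_high`, `p`, `single_instrument`.
#' @export
leave_one_out <- function(instruments, level = 0.95) {
  if (instruments$k < 2L) stop_validation("leave-one-out requires k >= 2")
  z <- stats::qnorm((1 + level) / 2)
  rows <- lapply(seq_len(instruments$k), function(j) {
    sub <- instrument_set(instruments$variant_id[-j],
                          instruments$beta_exposure[-j],
                          instruments$se_exposure[-j],
                          instruments$beta_outcome[-j],
                          instruments$se_outcome[-j])
    est <- ivw(sub)
    data.frame(dropped = instruments$variant_id[j], theta = est$theta,
               se = est$se, ci_low = est$theta - z * est$se,
               ci_high = est$theta + z * est$se, p = est$p,
               single_instrument = sub$k == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-variant association scan
#'
#' Regresses a target column on each variant's dosage in turn, with the same
#' covariates as the mediation models (age, sex, site when present, and the
#' supplied global covariate). Continuous targets use least squares, binary
#' targets a logistic model (coefficients on the log-odds scale). Variants
#' whose model fails (monomorphic dosage, non-convergence) are dropped with a
#' warning.
#'
#' @param data Analysis table from [derive_analysis_data()].
#' @param target Column name of the exposure or outcome to scan against.
#' @param variant_ids Dosage column names to scan.
#' @param family `"linear"` or `"logistic"`.
#' @param global_covariate Optional extra covariate column (e.g. `"icv"`).
#' @return data.frame with `variant_id`, `beta`, `se`.
#' @export
assoc_scan <- function(data, target, variant_ids,
                       family = c("linear", "logistic"),
                       global_covariate = NULL) {
  family <- match.arg(family)
  if (is.null(data[[target]])) stop_validation("target column '%s' absent", target)
  covs <- c("age", "sex", global_covariate)
  rows <- lapply(variant_ids, function(v) {
    ok <- complete_rows(data, c(v, target, covs))
    d <- data[ok, , drop = FALSE]
    res <- tryCatch({
      X <- design_matrix(d, c(v, covs))
      if (family == "linear") {
        fit <- ls_fit(X, d[[target]])
        c(fit$coef[[v]], fit$se[[v]])
      } else {
        fit <- logit_fit(X, d[[target]])
        if (!fit$converged) stop("non-convergence")
        c(fit$coef[[v]], fit$se[[v]])
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("variant %s dropped from association scan: model failed", v),
              call. = FALSE)
      return(NULL)
    }
    data.frame(variant_id = v, beta = res[1], se = res[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' One-sample bidirectional Mendelian randomization
#'
#' For each brain measure, estimates the causal effect of the measure on the
#' LOAD outcome (forward direction: exposure associations from the measure
#' scan, outcome associations from the LOAD scan) and of LOAD on the measure
#' (reverse direction), using IVW, weighted median and MR-Egger, together
#' with Cochran's Q, the I2_GX instrument-strength statistic and
#' leave-one-out IVW. P-values are Benjamini-Hochberg adjusted across
#' measures within each direction-method stratum.
#'
#' Exposure and outcome associations are estimated in the same participants
#' (one-sample design) with the mediation covariates; for a binary LOAD
#' outcome the reverse-direction exposure associations are logistic
#' coefficients on the log-odds scale.
#'
#' @param data Analysis table.
#' @param measures Measure catalog rows restricted to the measures of
#'   interest (typically the significant mediators).
#' @param variant_ids Instrument dosage columns.
#' @param outcome_family `"linear"` or `"logistic"`; default from the table
#'   attribute.
#' @param wm_boot,seed Weighted-median bootstrap draws and seed.
#' @param q FDR level across measures (default 0.05).
#' @return data.frame of class `mr_results`: one row per measure x direction
#'   x method with `theta`, `se`, `p`, `p_fdr`, `egger_intercept`,
#'   `egger_intercept_p`, `cochran_q`, `q_p`, `i2_gx`, `weak_instruments`,
#'   `k`. Leave-one-out tables are attached as attribute `leave_one_out`
#'   (a named list per measure and direction).
#' @export
run_bidirectional <- function(data, measures, variant_ids,
                              outcome_family = NULL, wm_boot = 200, seed = 1L,
                              q = 0.05) {
  if (is.null(outcome_family))
    outcome_family <- attr(data, "outcome_family") %||% "linear"
  rows <- list()
  loo <- list()
  for (k in seq_len(nrow(measures))) {
    nm <- measures$name[k]
    gcov <- global_covariate_for(measures$measure_type[k])
    bx_meas <- assoc_scan(data, nm, variant_ids, "linear", gcov)
    by_load <- assoc_scan(data, "outcome", variant_ids, outcome_family, gcov)
    shared <- intersect(bx_meas$variant_id, by_load$variant_id)
    bx_meas <- bx_meas[match(shared, bx_meas$variant_id), ]
    by_load <- by_load[match(shared, by_load$variant_id), ]
    for (direction in c("forward", "reverse")) {
      ins <- if (direction == "forward")
        instrument_set(shared, bx_meas$beta, bx_meas$se,
                       by_load$beta, by_load$se)
      else
        instrument_set(shared, by_load$beta, by_load$se,
                       bx_meas$beta, bx_meas$se)
      qstat <- cochran_q(ins)
      i2 <- i2_gx(ins)
      loo[[paste(nm, direction, sep = ".")]] <- leave_one_out(ins)
      ests <- list(ivw(ins),
                   weighted_median(ins, n_boot = wm_boot, seed = seed),
                   mr_egger(ins))
      for (est in ests) {
        rows[[length(rows) + 1L]] <- data.frame(
          measure = nm, direction = direction, method = est$method,
          k = ins$k, theta = est$theta, se = est$se, p = est$p,
          egger_intercept = est$intercept %||% NA_real_,
          egger_intercept_p = est$p_intercept %||% NA_real_,
          cochran_q = qstat$q, q_p = qstat$p,
          i2_gx = i2$i2_gx, weak_instruments = i2$weak_flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (direction in unique(out$direction)) {
    for (method in unique(out$method)) {
      sel <- out$direction == direction & out$method == method
      out$p_fdr[sel] <- bh_fdr(out$p[sel], q = q)$p_adjusted
    }
  }
  out$significant <- out$p_fdr <= q
  attr(out, "leave_one_out") <- loo
  class(out) <- c("mr_results", "data.frame")
  out
}
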