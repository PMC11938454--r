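#' Parameter-recovery simulation for the mediator model (path a)
#'
#' Validation harness: generates a cohort in which the true per-allele effect
#' of a variant on one standardized regional measure is known, then fits the
#' mediator regression through the package's own path-a interface and returns
#' the fitted coefficient. Used to confirm that published effect-size
#' estimates plugged in as ground truth are recovered within Monte-Carlo
#' tolerance.
#'
#' The cohort mimics a case-control neuroimaging sample: age
#' truncated-Gaussian (mean 76, SD 7.2), balanced sex, ICV, and a genotype
#' drawn from APOE haplotypes when `variant_id = "APOE4"` or Hardy-Weinberg
#' dosages otherwise. The measure is generated on the standardized scale with
#' unit residual SD. The global covariate matched to the measure type is an
#' independent standardized draw, so it costs a degree of freedom without
#' biasing the genotype coefficient.
#'
#' @param true_coef True standardized per-allele effect (SD of measure per
#'   allele).
#' @param variant_id `"APOE4"` or an rsID-style label.
#' @param region,measure_type Mediator identity (see [measure_catalog()]).
#' @param allele_frequency Effect-allele (or epsilon-4 haplotype) frequency.
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return List with `estimate`, `se`, `p`, `n`, `true_coef`.
#' @export
simulate_path_a_recovery <- function(true_coef, variant_id = "APOE4",
                                     region = "hippocampus",
                                     measure_type = "volume",
                                     allele_frequency = 0.15,
                                     n = 5000, seed = 1L) {
  d <- recovery_cohort(true_coef, variant_id, region, measure_type,
                       allele_frequency, n, seed)
  spec <- mediation_spec(variant_id, region, measure_type, "linear",
                         bootstrap_reps = 200, seed = seed)
  fit <- fit_path_a(d, spec)
  list(estimate = fit$estimate, se = fit$se, p = fit$p, n = fit$n,
       true_coef = true_coef)
}

#' Parameter-recovery simulation for the bootstrap indirect effect
#'
#' Generates a linear-outcome cohort in which the true indirect effect is
#' known by construction -- the mediator is drawn with path-a coefficient
#' `path_a` and the continuous outcome with path-b coefficient
#' `indirect_effect / path_a`, so the true product is exactly
#' `indirect_effect` -- and estimates it with [bootstrap_acme()].
#'
#' @param path_a True standardized genotype-to-measure coefficient.
#' @param indirect_effect True indirect (mediated) effect `a * b`.
#' @param direct_effect True direct effect on the outcome per allele.
#' @param bootstrap_reps Bootstrap resamples.
#' @inheritParams simulate_path_a_recovery
#' @return The `mediation_result` from [bootstrap_acme()], with the truth in
#'   fields `true_acme`, `true_a`.
#' @export
simulate_acme_recovery <- function(path_a, indirect_effect,
                                   variant_id = "APOE4",
                                   region = "entorhinal",
                                   measure_type = "thickness",
                                   allele_frequency = 0.15,
                                   direct_effect = 0.05,
                                   n = 10000, bootstrap_reps = 500,
                                   seed = 1L) {
  d <- recovery_cohort(path_a, variant_id, region, measure_type,
                       allele_frequency, n, seed)
  b <- indirect_effect / path_a
  measure <- d[[paste0(region, "__", measure_type)]]
  dosage <- d[[variant_id]]
  d$outcome <- direct_effect * dosage + b * measure +
    0.01 * (d$age - mean(d$age)) + stats::rnorm(n, 0, 1)
  spec <- mediation_spec(variant_id, region, measure_type, "linear",
                         bootstrap_reps = bootstrap_reps, seed = seed)
  res <- bootstrap_acme(d, spec)
  res$true_acme <- indirect_effect
  res$true_a <- path_a
  res
}

## Shared cohort builder for the recovery harnesses: analysis-style table
## with one variant, one measure on the standardized scale, covariates, and
## a placeholder outcome (overwritten by the ACME harness).
recovery_cohort <- function(true_coef, variant_id, region, measure_type,
                            allele_frequency, n, seed) {
  set.seed(seed)
  if (variant_id == "APOE4") {
    apoe <- generate_apoe_genotypes(n, c(e3 = 1 - allele_frequency,
                                         e4 = allele_frequency))
    dosage <- apoe$e4_count
  } else {
    dosage <- stats::rbinom(n, 2L, allele_frequency)
  }
  G <- matrix(as.integer(dosage), ncol = 1, dimnames = list(NULL, variant_id))
  covariates <- data.frame(age = rnorm_trunc(n, 76, 7.2, 40, 100),
                           sex = stats::rbinom(n, 1L, 0.5),
                           icv = stats::rnorm(n, 1.5e6, 1.5e5))
  measure <- paste0(region, "__", measure_type)
  panel <- list(variant_spec(variant_id, "C", allele_frequency,
                             mediator_effects = stats::setNames(true_coef,
                                                                measure)))
  mc <- measure_catalog()
  med <- generate_mediators(G, covariates, panel, residual_sd = 1,
                            measures = mc[mc$name == measure, , drop = FALSE])
  d <- cbind(covariates, med, as.data.frame(G))
  d$icv <- zscore(d$icv)
  gcov <- global_covariate_for(measure_type)
  if (gcov != "icv") d[[gcov]] <- stats::rnorm(n)
  d$outcome <- stats::rnorm(n)
  attr(d, "outcome_family") <- "linear"
  d
}
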