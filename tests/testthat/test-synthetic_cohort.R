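test_that("genotypes follow Hardy-Weinberg proportions at the specified frequency", {
  cfg <- cohort_config(50000, seed = 101)
  panel <- list(variant_spec("v1", "C", 0.2))
  G <- generate_genotypes(cfg, panel)
  props <- as.numeric(table(factor(G[, "v1"], levels = 0:2))) / nrow(G)
  ## Hardy-Weinberg expansion at q = 0.2: (0.64, 0.32, 0.04)
  expect_lt(max(abs(props - c(0.64, 0.32, 0.04))), 0.01)

  cfg2 <- cohort_config(10000, seed = 102)
  G2 <- generate_genotypes(cfg2, list(variant_spec("v1", "C", 0.5)))
  expect_lt(abs(mean(G2[, "v1"]) / 2 - 0.5), 0.02)
})

test_that("out-of-range allele frequencies are rejected", {
  expect_error(variant_spec("v1", "C", 0), class = "loadpaths_validation_error")
  expect_error(variant_spec("v1", "C", 1), class = "loadpaths_validation_error")
  expect_error(variant_spec("v1", "C", NaN), class = "loadpaths_validation_error")
  expect_error(variant_spec("v1", "Z", 0.5), class = "loadpaths_validation_error")
})

test_that("missingness is applied at the configured rate and genotypes are reproducible", {
  cfg <- cohort_config(20000, seed = 7, missing_rate = 0.05)
  panel <- list(variant_spec("v1", "C", 0.3), variant_spec("v2", "C", 0.1))
  G1 <- generate_genotypes(cfg, panel)
  G2 <- generate_genotypes(cfg, panel)
  expect_identical(G1, G2)
  expect_lt(abs(mean(is.na(G1)) - 0.05), 0.01)
  expect_error(generate_genotypes(cfg, list()), class = "loadpaths_validation_error")
  expect_error(
    generate_genotypes(cfg, list(variant_spec("a", "C", 0.5),
                                 variant_spec("a", "C", 0.5))),
    class = "loadpaths_validation_error")
})

test_that("APOE haplotype generator maps haplotypes to site genotypes correctly", {
  g4 <- generate_apoe_genotypes(50, c(e4 = 1), seed = 1)
  expect_true(all(g4$rs429358 == "C/C" & g4$rs7412 == "C/C" & g4$e4_count == 2L))
  g3 <- generate_apoe_genotypes(50, c(e3 = 1), seed = 2)
  expect_true(all(g3$rs429358 == "T/T" & g3$rs7412 == "C/C" & g3$e4_count == 0L))
  g2 <- generate_apoe_genotypes(50, c(e2 = 1), seed = 3)
  expect_true(all(g2$rs429358 == "T/T" & g2$rs7412 == "T/T" & g2$e4_count == 0L))

  ## random pairing: mean true count = 2 x haplotype frequency
  g <- generate_apoe_genotypes(50000, c(e3 = 0.85, e4 = 0.15), seed = 4)
  se <- sqrt(2 * 0.15 * 0.85 / 50000)
  expect_lt(abs(mean(g$e4_count) - 0.30), 3 * se)

  expect_error(generate_apoe_genotypes(10, c(e3 = 0.5, e4 = 0.4)),
               class = "loadpaths_validation_error")
  expect_error(generate_apoe_genotypes(10, c(bad = 1)),
               class = "loadpaths_validation_error")
})

test_that("mediator generation has the linear structure it claims", {
  ## noiseless identity: measure equals dosage exactly
  G <- matrix(c(0L, 1L, 2L, 1L, 0L), ncol = 1, dimnames = list(NULL, "v1"))
  cov <- data.frame(age = rep(70, 5), sex = rep(0L, 5))
  panel <- list(variant_spec("v1", "C", 0.5,
                             mediator_effects = c(hippocampus__volume = 1)))
  mc <- measure_catalog()
  med <- generate_mediators(G, cov, panel, residual_sd = 0,
                            measures = mc[mc$name == "hippocampus__volume", ],
                            covariate_effects = list(age = 0, sex = 0, icv = 0))
  expect_equal(med$hippocampus__volume, as.numeric(G[, 1]))

  ## null effects: fitted coefficient within its CI of zero
  set.seed(11)
  n <- 4000
  G <- matrix(rbinom(n, 2L, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
  cov <- data.frame(age = rnorm(n, 70, 7), sex = rbinom(n, 1, 0.5))
  panel <- list(variant_spec("v1", "C", 0.3))
  med <- generate_mediators(G, cov, panel, residual_sd = 1,
                            measures = mc[mc$name == "amygdala__volume", ],
                            seed = 12)
  fit <- summary(lm(med$amygdala__volume ~ G[, 1] + cov$age + cov$sex))
  expect_lt(abs(fit$coefficients[2, 1]), 3 * fit$coefficients[2, 2])

  ## coefficient recovery by OLS at n = 5000 (3-SE band)
  panel <- list(variant_spec("v1", "C", 0.3,
                             mediator_effects = c(amygdala__volume = -0.424)))
  n <- 5000
  set.seed(13)
  G <- matrix(rbinom(n, 2L, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
  cov <- data.frame(age = rnorm(n, 70, 7), sex = rbinom(n, 1, 0.5))
  med <- generate_mediators(G, cov, panel, residual_sd = 1,
                            measures = mc[mc$name == "amygdala__volume", ])
  fit <- summary(lm(med$amygdala__volume ~ G[, 1] + cov$age + cov$sex))
  expect_lt(abs(fit$coefficients[2, 1] + 0.424), 3 * fit$coefficients[2, 2])

  ## dimension mismatch and unknown measures are rejected
  expect_error(generate_mediators(G, cov[1:10, ], panel),
               class = "loadpaths_validation_error")
  bad <- list(variant_spec("v1", "C", 0.3,
                           mediator_effects = c(not_a_measure = 1)))
  expect_error(generate_mediators(G, cov, bad),
               class = "loadpaths_validation_error")
})

test_that("case-control outcome model is calibrated and respects conditioning", {
  ## null model at logit(0.5): case fraction about one half
  set.seed(21)
  n <- 20000
  G <- matrix(rbinom(n, 2L, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
  cov <- data.frame(age = rnorm(n, 70, 7), sex = rbinom(n, 1, 0.5))
  panel <- list(variant_spec("v1", "C", 0.3))
  cfg <- cohort_config(n, seed = 21, cohort_style = "case_control",
                       outcome_params = list(intercept = 0))
  med <- data.frame(row.names = seq_len(n))
  out <- generate_outcome(G, med, cov, panel, cfg, seed = 22)
  expect_lt(abs(mean(out$status) - 0.5), 3 * sqrt(0.25 / n))

  ## direct effect without mediator coupling: dosage associates with the
  ## outcome, the mediator does not once dosage is conditioned on
  panel <- list(variant_spec("v1", "C", 0.3,
                             mediator_effects = c(hippocampus__volume = 0.5),
                             direct_outcome_effect = 0.5))
  mc <- measure_catalog()
  med <- generate_mediators(G, cov, panel, residual_sd = 1,
                            measures = mc[mc$name == "hippocampus__volume", ],
                            seed = 23)
  out <- generate_outcome(G, med, cov, panel, cfg, seed = 24)
  refit <- summary(glm(out$status ~ G[, 1] + med$hippocampus__volume,
                       family = binomial()))
  z_dosage <- refit$coefficients[2, 3]
  z_mediator <- refit$coefficients[3, 3]
  expect_gt(z_dosage, 3)
  expect_lt(abs(z_mediator), 3)
})

test_that("proxy outcome induces a dosage correlation only through liability", {
  n <- 8000
  cfg <- cohort_config(n, seed = 31, cohort_style = "proxy")
  mc <- measure_catalog()

  sim_corr <- function(direct, seed) {
    set.seed(seed)
    G <- matrix(rbinom(n, 2L, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
    cov <- data.frame(age = rnorm(n, 70, 7), sex = rbinom(n, 1, 0.5))
    panel <- list(variant_spec("v1", "C", 0.3, direct_outcome_effect = direct))
    out <- generate_outcome(G, data.frame(row.names = seq_len(n)), cov, panel, cfg)
    score <- proxy_score(cbind(out$parent1_affected, out$parent2_affected),
                         cbind(out$parent1_age, out$parent2_age),
                         cbind(out$parent1_available, out$parent2_available))
    cor.test(score, G[, 1])
  }
  null_ct <- sim_corr(0, 32)
  expect_gt(null_ct$p.value, 0.01)
  risk_ct <- sim_corr(0.8, 33)
  expect_gt(risk_ct$estimate, 0)
  expect_lt(risk_ct$p.value, 1e-4)
})

test_that("a full simulated cohort is seed-deterministic and round-trips through TSV", {
  mc <- measure_catalog()
  meas <- mc[mc$name %in% c("hippocampus__volume", "brain_stem__volume",
                            "entorhinal__thickness", "entorhinal__area"), ]
  cfg <- cohort_config(200, seed = 41, cohort_style = "proxy", missing_rate = 0.02)
  panel <- synthetic_panel()
  co1 <- simulate_cohort(cfg, panel, meas)
  co2 <- simulate_cohort(cfg, panel, meas)
  expect_identical(co1$genotypes, co2$genotypes)
  expect_identical(co1$phenotypes, co2$phenotypes)

  dir <- withr::local_tempdir()
  write_cohort(co1, dir)
  back <- read_cohort(dir)
  expect_identical(dim(back$genotypes), dim(co1$genotypes))
  expect_equal(back$genotypes, co1$genotypes, ignore_attr = TRUE)
  expect_equal(back$phenotypes$age, co1$phenotypes$age, tolerance = 1e-8)
  expect_equal(back$config$cohort_style, "proxy")
  expect_equal(vapply(back$panel, function(v) v$allele_frequency, numeric(1)),
               vapply(panel, function(v) v$allele_frequency, numeric(1)))
})

test_that("empirical allele frequencies track the panel specification", {
  cfg <- cohort_config(30000, seed = 51)
  panel <- synthetic_panel()
  co <- simulate_cohort(cfg, panel, measure_catalog()[1:2, ])
  for (v in panel) {
    obs <- mean(co$genotypes[, v$variant_id], na.rm = TRUE) / 2
    se <- sqrt(v$allele_frequency * (1 - v$allele_frequency) / (2 * 30000))
    expect_lt(abs(obs - v$allele_frequency), 3 * se)
  }
})
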