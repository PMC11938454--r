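#' Variant specification
#'
#' Describes one genetic risk variant in a simulation panel: its effect
#' allele and population frequency, the standardized effects it exerts on
#' regional brain measures (path a of the mediation diagram), and any direct
#' effect on the outcome's linear predictor (path c-prime).
#'
#' @param variant_id Unique identifier (e.g. an rsID, or `"APOE4"` for the
#'   epsilon-4 allele count pseudo-variant).
#' @param effect_allele Single nucleotide character, one of A/C/G/T.
#' @param allele_frequency Effect-allele frequency, strictly inside (0, 1).
#' @param mediator_effects Named numeric vector mapping measure names
#'   (`<region>__<measure_type>`, see [measure_catalog()]) to standardized
#'   per-allele effects (SD of the measure per allele).
#' @param direct_outcome_effect Per-allele coefficient on the outcome's
#'   linear predictor not transmitted through any brain measure.
#' @return Object of class `variant_spec`.
#' @export
variant_spec <- function(variant_id, effect_allele, allele_frequency,
                         mediator_effects = numeric(0),
                         direct_outcome_effect = 0) {
  if (!is.character(variant_id) || length(variant_id) != 1L || !nzchar(variant_id))
    stop_validation("variant_id must be a non-empty string")
  if (!effect_allele %in% c("A", "C", "G", "T"))
    stop_validation("effect_allele must be one of A, C, G, T")
  check_scalar_number(allele_frequency, "allele_frequency", 0, 1,
                      open_lower = TRUE, open_upper = TRUE)
  if (length(mediator_effects) && is.null(names(mediator_effects)))
    stop_validation("mediator_effects must be a named vector of measure effects")
  check_scalar_number(direct_outcome_effect, "direct_outcome_effect")
  structure(list(variant_id = variant_id,
                 effect_allele = effect_allele,
                 allele_frequency = allele_frequency,
                 mediator_effects = mediator_effects,
                 direct_outcome_effect = direct_outcome_effect),
            class = "variant_spec")
}

#' Cohort simulation configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults emulate the two
#' cohort designs the analysis targets: `"proxy"` cohorts carry parental LOAD
#' history from which a family-history proxy score is derived (biobank-style:
#' mean age 64.4, SD 7.7, 47.7% male, 3 assessment sites), and
#' `"case_control"` cohorts carry a clinical case/control status
#' (mean age 76, SD 7.2, single site).
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   it.
#' @param cohort_style `"proxy"` or `"case_control"`.
#' @param age_mean,age_sd Age distribution in years (Gaussian truncated to
#'   40-100).
#' @param sex_ratio Proportion male.
#' @param n_sites Number of assessment sites (>= 1).
#' @param mediator_residual_sd Residual SD of the regional measures on the
#'   standardized scale (> 0).
#' @param missing_rate Per-genotype missing-completely-at-random rate.
#' @param outcome_params List of outcome-model parameters:
#'   `intercept` (logit scale; for proxy cohorts the per-parent affection
#'   intercept), `age` and `sex` coefficients on the linear predictor,
#'   `mediator_coefs` (named vector, path-b coefficients per measure),
#'   `transmission` (attenuation of the participant's genetic liability when
#'   projected onto a parent; 0.5 for one meiosis), `parent_age_mean`,
#'   `parent_age_sd` and `parent_available_rate`. Unused entries are ignored
#'   for the other cohort style.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants,
                          seed = 1L,
                          cohort_style = c("proxy", "case_control"),
                          age_mean = NULL, age_sd = NULL,
                          sex_ratio = NULL,
                          n_sites = NULL,
                          mediator_residual_sd = 1,
                          missing_rate = 0,
                          outcome_params = list()) {
  cohort_style <- match.arg(cohort_style)
  check_scalar_number(n_participants, "n_participants", 1)
  check_scalar_number(mediator_residual_sd, "mediator_residual_sd", 0,
                      open_lower = TRUE)
  check_scalar_number(missing_rate, "missing_rate", 0, 1, open_upper = TRUE)
  is_proxy <- cohort_style == "proxy"
  if (is.null(age_mean)) age_mean <- if (is_proxy) 64.4 else 76
  if (is.null(age_sd)) age_sd <- if (is_proxy) 7.7 else 7.2
  if (is.null(sex_ratio)) sex_ratio <- if (is_proxy) 0.477 else 0.5
  if (is.null(n_sites)) n_sites <- if (is_proxy) 3L else 1L
  check_scalar_number(sex_ratio, "sex_ratio", 0, 1)
  check_scalar_number(n_sites, "n_sites", 1)
  defaults <- list(intercept = if (is_proxy) stats::qlogis(0.118)
                               else stats::qlogis(0.469),
                   age = 0, sex = 0,
                   mediator_coefs = numeric(0),
                   transmission = 0.5,
                   parent_age_mean = 75, parent_age_sd = 10,
                   parent_available_rate = 1)
  outcome_params <- utils::modifyList(defaults, outcome_params)
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 cohort_style = cohort_style,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_ratio = sex_ratio, n_sites = as.integer(n_sites),
                 mediator_residual_sd = mediator_residual_sd,
                 missing_rate = missing_rate,
                 outcome_params = outcome_params),
            class = "cohort_config")
}

#' Draw genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each variant's dosage (count of effect alleles, 0/1/2) is drawn
#' independently as Binomial(2, allele frequency), i.e. Hardy-Weinberg
#' proportions; missingness, if requested, is applied completely at random.
#' Variants are independent: the generator does not emulate linkage
#' disequilibrium.
#'
#' @param config A [cohort_config()]. `config$seed` is used unless the
#'   calling code has already seeded the stream (`seed = FALSE`).
#' @param panel Non-empty list of [variant_spec()] objects with unique ids.
#' @param seed Set to `FALSE` to draw from the current random stream.
#' @return Integer matrix (participants x variants) with `NA` for missing
#'   genotypes; column names are the variant ids.
#' @export
generate_genotypes <- function(config, panel, seed = TRUE) {
  if (!length(panel)) stop_validation("panel must be non-empty")
  ids <- vapply(panel, function(v) v$variant_id, character(1))
  if (anyDuplicated(ids)) stop_validation("duplicate variant_id in panel")
  for (v in panel)
    check_scalar_number(v$allele_frequency, paste0("allele_frequency[", v$variant_id, "]"),
                        0, 1, open_lower = TRUE, open_upper = TRUE)
  if (isTRUE(seed)) set.seed(config$seed)
  n <- config$n_participants
  G <- vapply(panel, function(v) stats::rbinom(n, 2L, v$allele_frequency),
              integer(n))
  G <- matrix(G, nrow = n, dimnames = list(NULL, ids))
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * length(panel)) < config$missing_rate,
                   nrow = n)
    G[miss] <- NA_integer_
  }
  G
}

## Nucleotides carried by each APOE haplotype at (rs429358, rs7412).
apoe_haplotype_map <- function() {
  list(e1 = c("C", "T"), e2 = c("T", "T"), e3 = c("T", "C"), e4 = c("C", "C"))
}

#' Draw APOE genotypes from haplotype frequencies
#'
#' Each participant receives two APOE haplotypes drawn independently from the
#' supplied frequencies. The haplotypes determine the unphased genotypes at
#' rs429358 and rs7412 through the standard coding (epsilon-1 = C+T,
#' epsilon-2 = T+T, epsilon-3 = T+C, epsilon-4 = C+C at rs429358+rs7412).
#' The true epsilon-4 allele count is retained so that genotype-based allele
#' counting can be checked against it.
#'
#' @param n Number of participants.
#' @param haplotype_frequencies Named numeric vector over a subset of
#'   `c("e1","e2","e3","e4")`, summing to 1. The epsilon-1 haplotype is
#'   negligibly rare in European populations and is omitted from the default.
#' @param seed Optional integer seed; `NULL` draws from the current stream.
#' @return data.frame with columns `rs429358`, `rs7412` (unphased genotype
#'   strings such as `"C/T"`, alphabetically ordered) and `e4_count`
#'   (true count, 0-2).
#' @export
generate_apoe_genotypes <- function(n, haplotype_frequencies = c(e3 = 0.85, e4 = 0.15),
                                    seed = NULL) {
  check_scalar_number(n, "n", 1)
  hmap <- apoe_haplotype_map()
  nm <- names(haplotype_frequencies)
  if (is.null(nm) || !all(nm %in% names(hmap)))
    stop_validation("haplotype_frequencies must be named with e1/e2/e3/e4")
  if (any(haplotype_frequencies < 0) ||
      abs(sum(haplotype_frequencies) - 1) > 1e-6)
    stop_validation("haplotype frequencies must be non-negative and sum to 1")
  if (!is.null(seed)) set.seed(seed)
  h1 <- sample(nm, n, replace = TRUE, prob = haplotype_frequencies)
  h2 <- sample(nm, n, replace = TRUE, prob = haplotype_frequencies)
  site_geno <- function(site_idx) {
    a <- vapply(h1, function(h) hmap[[h]][site_idx], character(1))
    b <- vapply(h2, function(h) hmap[[h]][site_idx], character(1))
    paste(pmin(a, b), pmax(a, b), sep = "/")
  }
  data.frame(rs429358 = site_geno(1L), rs7412 = site_geno(2L),
             e4_count = as.integer((h1 == "e4") + (h2 == "e4")),
             stringsAsFactors = FALSE)
}

#' Simulate regional brain measures from a linear mediator model
#'
#' Each measure is generated on the combined-hemisphere, standardized scale
#' as the sum of per-variant genetic effects (dosage times the variant's
#' standardized `mediator_effects` entry), covariate effects, and Gaussian
#' noise. This is exactly the linear structure the mediator model (path a)
#' of the analysis assumes, so generating coefficients are recoverable by
#' least squares.
#'
#' @param genotypes Dosage matrix from [generate_genotypes()] (columns named
#'   by variant id). Missing dosages contribute their expected value (twice
#'   the sample allele frequency) to the mediator, mimicking an unobserved
#'   true genotype.
#' @param covariates data.frame with columns `age` (years), `sex` (0/1) and,
#'   for volume measures, `icv`; row count must match `genotypes`.
#' @param panel List of [variant_spec()]; `mediator_effects` names must be
#'   measure names from `measures`.
#' @param residual_sd Residual standard deviation (> 0 unless exactly 0 for
#'   noiseless toys).
#' @param measures Measure catalog rows to generate (default: all 93).
#' @param covariate_effects List with per-year `age` effect (on the centered
#'   age), `sex` effect, and `icv` loading applied to volume measures only
#'   (on the scaled ICV).
#' @param seed Optional integer seed.
#' @return data.frame of generated measures, one column per catalog `name`.
#' @export
generate_mediators <- function(genotypes, covariates, panel, residual_sd = 1,
                               measures = measure_catalog(),
                               covariate_effects = list(age = -0.01, sex = 0.05,
                                                        icv = 0.3),
                               seed = NULL) {
  n <- nrow(genotypes)
  if (nrow(covariates) != n)
    stop_validation("genotypes (%d rows) and covariates (%d rows) do not match",
                    n, nrow(covariates))
  check_scalar_number(residual_sd, "residual_sd", 0)
  known <- measures$name
  for (v in panel) {
    bad <- setdiff(names(v$mediator_effects), known)
    if (length(bad))
      stop_validation("unknown measure(s) in mediator_effects of %s: %s",
                      v$variant_id, paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  ## dosages with missing entries replaced by their expectation
  G <- genotypes
  for (j in seq_len(ncol(G))) {
    m <- is.na(G[, j])
    if (any(m)) G[m, j] <- mean(G[!m, j])
  }
  age_c <- covariates$age - mean(covariates$age)
  icv_z <- if (!is.null(covariates$icv)) as.numeric(scale(covariates$icv)) else 0
  out <- matrix(0, nrow = n, ncol = nrow(measures),
                dimnames = list(NULL, measures$name))
  for (k in seq_len(nrow(measures))) {
    nm <- measures$name[k]
    val <- covariate_effects$age * age_c + covariate_effects$sex * covariates$sex
    if (measures$measure_type[k] == "volume")
      val <- val + covariate_effects$icv * icv_z
    for (v in panel) {
      eff <- v$mediator_effects[nm]
      if (!is.na(eff)) val <- val + eff * G[, v$variant_id]
    }
    if (residual_sd > 0) val <- val + stats::rnorm(n, 0, residual_sd)
    out[, k] <- val
  }
  as.data.frame(out)
}

#' Simulate the LOAD outcome
#'
#' For `case_control` cohorts, a binary status is drawn from a logistic model
#' whose linear predictor combines the variants' direct effects, the
#' mediators' path-b coefficients, and covariate terms. For `proxy` cohorts,
#' two parental records are generated per participant: each parent's
#' affection probability is logistic in the participant's own genetic
#' liability attenuated by the transmission factor (one meiosis transmits
#' half the participant's allele dosage in expectation), and parental ages
#' are Gaussian truncated to 40-100 years. The resulting family-history proxy
#' score therefore correlates positively with risk dosage whenever the
#' genetic liability is non-null.
#'
#' @param genotypes Dosage matrix (missing entries contribute their column
#'   mean, as in [generate_mediators()]).
#' @param mediators Measure data.frame from [generate_mediators()].
#' @param covariates data.frame with `age` and `sex`.
#' @param panel List of [variant_spec()] supplying `direct_outcome_effect`
#'   per variant.
#' @param config A [cohort_config()]; `cohort_style` and `outcome_params`
#'   control the model.
#' @param seed Optional integer seed.
#' @return For `case_control`: data.frame with column `status` (0/1). For
#'   `proxy`: data.frame with `parent1_affected`, `parent1_age`,
#'   `parent1_available` and the same for `parent2`.
#' @export
generate_outcome <- function(genotypes, mediators, covariates, panel, config,
                             seed = NULL) {
  if (!inherits(config, "cohort_config") ||
      !config$cohort_style %in% c("proxy", "case_control"))
    stop_validation("config must be a cohort_config with a known cohort_style")
  op <- config$outcome_params
  n <- nrow(genotypes)
  if (!is.null(seed)) set.seed(seed)
  G <- genotypes
  for (j in seq_len(ncol(G))) {
    m <- is.na(G[, j])
    if (any(m)) G[m, j] <- mean(G[!m, j])
  }
  ## direct (non-mediated) genetic contribution to the linear predictor
  direct_lp <- rep(0, n)
  for (v in panel)
    if (v$direct_outcome_effect != 0)
      direct_lp <- direct_lp + v$direct_outcome_effect * G[, v$variant_id]
  ## mediated contribution via path-b coefficients on the generated measures
  med_lp <- rep(0, n)
  bc <- op$mediator_coefs
  if (length(bc)) {
    bad <- setdiff(names(bc), names(mediators))
    if (length(bad))
      stop_validation("mediator_coefs name unknown measure(s): %s",
                      paste(bad, collapse = ", "))
    for (nm in names(bc)) med_lp <- med_lp + bc[[nm]] * mediators[[nm]]
  }
  age_c <- covariates$age - mean(covariates$age)
  cov_lp <- op$age * age_c + op$sex * covariates$sex

  if (config$cohort_style == "case_control") {
    eta <- op$intercept + direct_lp + med_lp + cov_lp
    return(data.frame(status = stats::rbinom(n, 1L, stats::plogis(eta))))
  }

  ## proxy style: the participant's genetic liability (direct plus the
  ## genetically transmitted part of the mediated path) is attenuated by the
  ## transmission factor and drives each parent's affection probability.
  gen_med_lp <- rep(0, n)
  if (length(bc)) {
    for (nm in names(bc)) {
      for (v in panel) {
        eff <- v$mediator_effects[nm]
        if (!is.na(eff)) gen_med_lp <- gen_med_lp + bc[[nm]] * eff * G[, v$variant_id]
      }
    }
  }
  liability <- direct_lp + gen_med_lp
  p_aff <- stats::plogis(op$intercept + op$transmission * liability)
  parent <- function() {
    data.frame(affected = stats::rbinom(n, 1L, p_aff) == 1L,
               age = rnorm_trunc(n, op$parent_age_mean, op$parent_age_sd, 40, 100),
               available = stats::runif(n) < op$parent_available_rate)
  }
  p1 <- parent(); p2 <- parent()
  p1$age[!p1$available] <- NA_real_; p2$age[!p2$available] <- NA_real_
  p1$affected[!p1$available] <- NA; p2$affected[!p2$available] <- NA
  data.frame(parent1_affected = p1$affected, parent1_age = p1$age,
             parent1_available = p1$available,
             parent2_affected = p2$affected, parent2_age = p2$age,
             parent2_available = p2$available)
}

#' Simulate a complete synthetic cohort
#'
#' Draws genotypes (APOE epsilon-4 via haplotypes when the panel contains a
#' variant named `"APOE4"`, plain Hardy-Weinberg dosages otherwise),
#' covariates (age truncated-Gaussian in 40-100, sex, site, ICV), regional
#' brain measures from the linear mediator model, and the outcome, all from
#' the single seed in `config`. Measures are stored the way cohort exports
#' arrive in practice: split into left/right hemisphere columns for lateral
#' structures (sum-preserving for area and volume, mean-preserving for
#' thickness) so that downstream hemisphere combination is exercised.
#'
#' @param config A [cohort_config()].
#' @param panel List of [variant_spec()].
#' @param measures Measure catalog subset to generate (default all 93).
#' @return Object of class `load_cohort`: list with `genotypes` (dosage
#'   matrix), `apoe` (rs429358/rs7412 genotypes and true count, or NULL),
#'   `phenotypes` (covariates, outcome columns, hemisphere-level measures),
#'   `panel`, `config`, `measures`, and `truth` (the generated
#'   combined-scale measures, for oracle checks).
#' @export
simulate_cohort <- function(config, panel, measures = measure_catalog()) {
  set.seed(config$seed)
  n <- config$n_participants
  ids <- vapply(panel, function(v) v$variant_id, character(1))
  apoe_idx <- which(ids == "APOE4")
  snp_panel <- if (length(apoe_idx)) panel[-apoe_idx] else panel
  G <- if (length(snp_panel))
    generate_genotypes(config, snp_panel, seed = FALSE)
  else
    matrix(integer(0), nrow = n, ncol = 0)
  apoe <- NULL
  if (length(apoe_idx)) {
    f4 <- panel[[apoe_idx]]$allele_frequency
    apoe <- generate_apoe_genotypes(n, c(e3 = 1 - f4, e4 = f4))
    dose <- apoe$e4_count
    if (config$missing_rate > 0)
      dose[stats::runif(n) < config$missing_rate] <- NA_integer_
    G <- cbind(G, APOE4 = dose)
  }
  G <- G[, ids, drop = FALSE]

  covariates <- data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    age = rnorm_trunc(n, config$age_mean, config$age_sd, 40, 100),
    sex = as.integer(stats::runif(n) < config$sex_ratio),
    site = paste0("site", 1L + (seq_len(n) - 1L) %% config$n_sites),
    icv = stats::rnorm(n, 1.5e6, 1.5e5)
  )
  med <- generate_mediators(G, covariates, panel, config$mediator_residual_sd,
                            measures = measures)
  outcome <- generate_outcome(G, med, covariates, panel, config)

  ## split combined-scale measures into hemisphere columns
  hemi <- split_hemispheres(med, measures)
  phen <- cbind(covariates, outcome, hemi)
  structure(list(genotypes = G, apoe = apoe, phenotypes = phen,
                 panel = panel, config = config, measures = measures,
                 truth = med),
            class = "load_cohort")
}

## Lateral structures get L/R columns whose sum (area, volume) or mean
## (thickness) reproduces the combined value exactly; midline volumes keep a
## single column. Cortical regions are all lateral.
split_hemispheres <- function(med, measures) {
  noncort <- noncortical_regions()
  midline <- noncort$region[!noncort$lateral]
  n <- nrow(med)
  out <- list()
  for (k in seq_len(nrow(measures))) {
    nm <- measures$name[k]
    type <- measures$measure_type[k]
    region <- measures$region[k]
    if (type == "volume" && region %in% midline) {
      out[[nm]] <- med[[nm]]
      next
    }
    u <- stats::rnorm(n, 0, 0.1)
    if (type == "thickness") {
      out[[paste0(nm, "__L")]] <- med[[nm]] + u
      out[[paste0(nm, "__R")]] <- med[[nm]] - u
    } else {
      out[[paste0(nm, "__L")]] <- med[[nm]] / 2 + u
      out[[paste0(nm, "__R")]] <- med[[nm]] / 2 - u
    }
  }
  as.data.frame(out, check.names = FALSE)
}

#' Write a cohort to disk in the package's exchange formats
#'
#' Writes `genotypes.tsv` (participant_id plus one dosage column per variant,
#' missing as empty cells), `phenotypes.tsv`, and `params.json` recording the
#' generating configuration and seed.
#'
#' @param cohort A `load_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(dir, "genotypes.tsv")
  ppath <- file.path(dir, "phenotypes.tsv")
  jpath <- file.path(dir, "params.json")
  gdf <- data.frame(participant_id = cohort$phenotypes$participant_id,
                    cohort$genotypes, check.names = FALSE)
  utils::write.table(gdf, gpath, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  utils::write.table(cohort$phenotypes, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  params <- list(
    config = unclass(cohort$config),
    panel = lapply(cohort$panel, function(v) {
      u <- unclass(v)
      u$mediator_effects <- as.list(u$mediator_effects)
      u
    })
  )
  jsonlite::write_json(params, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(genotypes = gpath, phenotypes = ppath, params = jpath))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `genotypes.tsv`, `phenotypes.tsv` and
#'   `params.json`.
#' @return A `load_cohort` (without the generator's `truth` table).
#' @export
read_cohort <- function(dir) {
  gdf <- utils::read.table(file.path(dir, "genotypes.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE,
                           na.strings = "", stringsAsFactors = FALSE)
  phen <- utils::read.table(file.path(dir, "phenotypes.tsv"), sep = "\t",
                            header = TRUE, check.names = FALSE,
                            na.strings = "", stringsAsFactors = FALSE)
  params <- jsonlite::read_json(file.path(dir, "params.json"))
  G <- as.matrix(gdf[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  cfg <- params$config
  config <- cohort_config(cfg$n_participants, cfg$seed, cfg$cohort_style,
                          cfg$age_mean, cfg$age_sd, cfg$sex_ratio, cfg$n_sites,
                          cfg$mediator_residual_sd, cfg$missing_rate,
                          lapply(cfg$outcome_params, function(x)
                            if (is.list(x)) unlist(x) else x))
  panel <- lapply(params$panel, function(v)
    variant_spec(v$variant_id, v$effect_allele, v$allele_frequency,
                 unlist(v$mediator_effects) %||% numeric(0),
                 v$direct_outcome_effect))
  structure(list(genotypes = G, apoe = NULL, phenotypes = phen,
                 panel = panel, config = config,
                 measures = measure_catalog(), truth = NULL),
            class = "load_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
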