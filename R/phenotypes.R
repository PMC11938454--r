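#' Count APOE epsilon-4 alleles from rs429358 and rs7412 genotypes
#'
#' The APOE haplotype is defined by the nucleotides at rs429358 and rs7412:
#' epsilon-1 = C+T, epsilon-2 = T+T, epsilon-3 = T+C, epsilon-4 = C+C. Given
#' unphased genotypes at the two sites, all haplotype-pair assignments
#' consistent with the genotypes are enumerated and the epsilon-4 count read
#' off. The only ambiguous configuration is the double heterozygote
#' (C/T at both sites), compatible with epsilon-2/epsilon-4 or
#' epsilon-1/epsilon-3; because epsilon-1 is vanishingly rare, it is resolved
#' as epsilon-2/epsilon-4 (count 1) and flagged.
#'
#' @param rs429358_genotype,rs7412_genotype Unphased genotype strings such as
#'   `"C/T"` (allele order irrelevant), or `NA`.
#' @return data.frame with columns `e4_count` (integer 0-2, `NA` when either
#'   genotype is missing) and `ambiguous` (logical). Vectorised over inputs.
#' @export
count_apoe4 <- function(rs429358_genotype, rs7412_genotype) {
  n <- max(length(rs429358_genotype), length(rs7412_genotype))
  g1 <- rep_len(rs429358_genotype, n)
  g2 <- rep_len(rs7412_genotype, n)
  parse_geno <- function(g, site) {
    if (is.na(g)) return(NULL)
    al <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (length(al) != 2L || !all(al %in% c("C", "T")))
      stop_validation("invalid %s genotype '%s': alleles must be C or T", site, g)
    al
  }
  e4 <- integer(n); amb <- logical(n)
  for (i in seq_len(n)) {
    a <- parse_geno(g1[i], "rs429358")
    b <- parse_geno(g2[i], "rs7412")
    if (is.null(a) || is.null(b)) { e4[i] <- NA_integer_; amb[i] <- NA; next }
    ## two ways to phase: pair a[1] with b[1], or a[1] with b[2]
    counts <- ambigs <- integer(0)
    for (perm in list(c(1L, 2L), c(2L, 1L))) {
      hap1 <- c(a[1], b[perm[1]]); hap2 <- c(a[2], b[perm[2]])
      counts <- c(counts, sum(identical(hap1, c("C", "C")),
                              identical(hap2, c("C", "C"))))
      ambigs <- c(ambigs, sum(identical(hap1, c("C", "T")),
                              identical(hap2, c("C", "T"))))
    }
    if (counts[1] == counts[2]) {
      e4[i] <- counts[1]; amb[i] <- FALSE
    } else {
      ## double heterozygote: prefer the phasing without epsilon-1
      pick <- which.min(ambigs)
      e4[i] <- counts[pick]; amb[i] <- TRUE
    }
  }
  data.frame(e4_count = e4, ambiguous = amb)
}

#' Family-history LOAD proxy score
#'
#' Sums one contribution per available parent: 1 for a parent affected by
#' LOAD, and for an unaffected parent an age-based weight
#' `(100 - age) / 100` capped at 0.32 (the maximum population prevalence of
#' AD) and floored at 0 for parents older than 100. Participants with no
#' available parental information receive `NA` and are excluded from
#' proxy-outcome models.
#'
#' @param affected Logical matrix or data.frame, one column per parent.
#' @param age Numeric matrix/data.frame of parental ages (current age or age
#'   at death), same shape.
#' @param available Logical matrix/data.frame, same shape; `NULL` treats
#'   every parent with non-missing status as available.
#' @return Numeric vector of proxy scores in \[0, number of parents\].
#' @export
proxy_score <- function(affected, age, available = NULL) {
  affected <- as.matrix(affected); age <- as.matrix(age)
  if (!all(dim(affected) == dim(age)))
    stop_validation("affected and age must have the same shape")
  if (is.null(available)) available <- !is.na(affected)
  available <- as.matrix(available)
  available[is.na(available)] <- FALSE
  if (any(age[available & affected == FALSE] < 0, na.rm = TRUE))
    stop_validation("negative parental age")
  contrib <- matrix(0, nrow(affected), ncol(affected))
  unaff <- available & !is.na(affected) & !affected
  if (any(is.na(age[unaff])))
    stop_validation("available unaffected parent with missing age")
  contrib[unaff] <- pmin(0.32, pmax(0, (100 - age[unaff]) / 100))
  aff <- available & !is.na(affected) & affected
  contrib[aff] <- 1
  score <- rowSums(contrib)
  score[rowSums(available) == 0] <- NA_real_
  score
}

#' Combine left and right hemisphere measures
#'
#' Surface areas and volumes are summed across hemispheres; mean thicknesses
#' are averaged. A missing hemisphere yields a missing combined value, so the
#' participant drops out of models using that measure.
#'
#' @param left,right Numeric vectors.
#' @param measure_type `"area"`, `"thickness"` or `"volume"`.
#' @return Numeric vector of combined values.
#' @export
combine_hemispheres <- function(left, right, measure_type) {
  measure_type <- match.arg(measure_type, c("area", "thickness", "volume"))
  out <- if (measure_type == "thickness") (left + right) / 2 else left + right
  out[!is.finite(left) | !is.finite(right)] <- NA_real_
  out
}

#' Global brain measures from regional cortical values
#'
#' Total surface area is the sum of the 34 cortical regional areas. Global
#' mean thickness is the surface-area-weighted mean of the 34 regional mean
#' thicknesses, each region weighted by its share of the total surface area.
#'
#' @param area data.frame/matrix of combined regional areas, columns named by
#'   cortical region.
#' @param thickness Same for regional mean thicknesses.
#' @return data.frame with columns `total_area` and `global_thickness`.
#' @export
global_measures <- function(area, thickness) {
  regions <- cortical_regions()
  miss_a <- setdiff(regions, colnames(area))
  miss_t <- setdiff(regions, colnames(thickness))
  if (length(miss_a) || length(miss_t))
    stop_validation("missing cortical region(s): %s",
                    paste(unique(c(miss_a, miss_t)), collapse = ", "))
  A <- as.matrix(area[, regions, drop = FALSE])
  Th <- as.matrix(thickness[, regions, drop = FALSE])
  total <- rowSums(A)
  gthick <- rowSums(A * Th) / total
  data.frame(total_area = total, global_thickness = gthick)
}

#' Z-score a column
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n-1
#' denominator), computed on the non-missing values; missing values stay
#' missing.
#'
#' @param x Numeric vector with at least two non-missing values.
#' @return Standardized vector.
#' @export
zscore <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2L) stop_validation("zscore needs >= 2 non-missing values")
  s <- stats::sd(v)
  if (s == 0) stop_validation("zscore undefined for a constant column")
  (x - mean(v)) / s
}

#' Genotype quality control
#'
#' Per variant: the missingness fraction and a 1-degree-of-freedom chi-square
#' Hardy-Weinberg test comparing observed genotype counts with expectations
#' at the sample allele frequency. A variant passes when missingness is at
#' most 10% and the HWE p-value is at least 1e-9. Monomorphic variants admit
#' no test; their HWE p is defined as 1 and they are flagged.
#'
#' @param genotypes Dosage matrix (0/1/2 with `NA`), columns named by variant.
#' @param max_missing Maximum tolerated missingness fraction (default 0.10).
#' @param hwe_min_p Minimum tolerated HWE p-value (default 1e-9).
#' @return data.frame with columns `variant_id`, `missingness`, `hwe_p`,
#'   `monomorphic`, `passed`.
#' @export
qc_variants <- function(genotypes, max_missing = 0.10, hwe_min_p = 1e-9) {
  ids <- colnames(genotypes)
  out <- lapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    miss <- mean(is.na(g))
    g <- g[!is.na(g)]
    if (length(g) && !all(g %in% 0:2))
      stop_validation("dosages of %s outside {0,1,2,NA}", ids[j])
    counts <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    n <- sum(counts)
    q <- if (n > 0) (counts[2] + 2 * counts[3]) / (2 * n) else NA_real_
    mono <- is.na(q) || q == 0 || q == 1
    if (mono) {
      p <- 1
    } else {
      expct <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
      chi2 <- sum((counts - expct)^2 / expct)
      p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    }
    data.frame(variant_id = ids[j], missingness = miss, hwe_p = p,
               monomorphic = mono,
               passed = miss <= max_missing && p >= hwe_min_p)
  })
  do.call(rbind, out)
}

#' Build the analysis table for a cohort
#'
#' Applies the full phenotype-derivation chain to a `load_cohort` (or to
#' tables read back from disk): hemisphere combination for every catalog
#' measure, total surface area and global mean thickness from the cortical
#' regions, the outcome column (family-history proxy score for proxy cohorts,
#' case/control status otherwise), z-scoring of all regional measures and of
#' the global covariates, and the genotype dosage columns.
#'
#' @param cohort A `load_cohort`.
#' @param standardize Z-score regional measures and global covariates
#'   (default TRUE, as the models expect).
#' @return data.frame with one row per participant: `participant_id`, `age`,
#'   `sex`, `site`, `icv`, `outcome`, `outcome_family` attribute
#'   (`"linear"` or `"logistic"`), global covariates `total_area`,
#'   `global_thickness`, all measure columns named `<region>__<type>`, and
#'   one dosage column per panel variant.
#' @export
derive_analysis_data <- function(cohort, standardize = TRUE) {
  phen <- cohort$phenotypes
  measures <- cohort$measures
  noncort <- noncortical_regions()
  midline <- noncort$region[!noncort$lateral]
  comb <- list()
  for (k in seq_len(nrow(measures))) {
    nm <- measures$name[k]
    type <- measures$measure_type[k]
    if (type == "volume" && measures$region[k] %in% midline) {
      comb[[nm]] <- phen[[nm]]
    } else {
      comb[[nm]] <- combine_hemispheres(phen[[paste0(nm, "__L")]],
                                        phen[[paste0(nm, "__R")]], type)
    }
  }
  comb <- as.data.frame(comb, check.names = FALSE)

  cort_present <- all(paste0(cortical_regions(), "__area") %in% names(comb)) &&
    all(paste0(cortical_regions(), "__thickness") %in% names(comb))
  if (cort_present) {
    area <- comb[, paste0(cortical_regions(), "__area")]
    colnames(area) <- cortical_regions()
    thick <- comb[, paste0(cortical_regions(), "__thickness")]
    colnames(thick) <- cortical_regions()
    glob <- global_measures(area, thick)
  } else {
    ## partial catalogs (reduced simulations): fall back to sums over what is
    ## present so the global covariate still exists
    a_cols <- grep("__area$", names(comb), value = TRUE)
    t_cols <- grep("__thickness$", names(comb), value = TRUE)
    zero <- rep(0, nrow(phen))
    glob <- data.frame(
      total_area = if (length(a_cols)) rowSums(comb[, a_cols, drop = FALSE]) else zero,
      global_thickness = if (length(t_cols)) rowMeans(comb[, t_cols, drop = FALSE]) else zero
    )
  }

  if (cohort$config$cohort_style == "proxy") {
    outcome <- proxy_score(
      cbind(phen$parent1_affected, phen$parent2_affected),
      cbind(phen$parent1_age, phen$parent2_age),
      cbind(phen$parent1_available, phen$parent2_available))
    family <- "linear"
  } else {
    outcome <- phen$status
    family <- "logistic"
  }

  if (standardize) {
    for (nm in names(comb)) comb[[nm]] <- zscore(comb[[nm]])
    for (nm in names(glob))
      if (isTRUE(stats::sd(glob[[nm]]) > 0)) glob[[nm]] <- zscore(glob[[nm]])
    icv <- zscore(phen$icv)
  } else {
    icv <- phen$icv
  }

  out <- data.frame(participant_id = phen$participant_id,
                    age = phen$age, sex = phen$sex, site = phen$site,
                    icv = icv, outcome = outcome,
                    stringsAsFactors = FALSE)
  out <- cbind(out, glob, comb, as.data.frame(cohort$genotypes))
  attr(out, "outcome_family") <- family
  out
}

#' Read genotype dosages from a VCF file
#'
#' Optional input dialect: converts the GT fields of diploid, biallelic VCF
#' records to effect-allele (ALT) dosage counts. Multi-allelic records are
#' dropped with a warning; missing genotypes become `NA`.
#'
#' @param path Path to a VCF (plain or bgzipped) readable by the vcfR
#'   package.
#' @return Integer dosage matrix, participants in rows (named by VCF sample),
#'   variants in columns (named by the ID field, falling back to
#'   `chrom:pos`).
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_validation("reading VCF input requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warning(sprintf("%d multi-allelic record(s) dropped", sum(!bi)),
            call. = FALSE)
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  fallback <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  ids[is.na(ids) | ids == "."] <- fallback[is.na(ids) | ids == "."]
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L || any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  })
  out <- t(dose)
  colnames(out) <- ids
  storage.mode(out) <- "integer"
  out
}
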