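Package: loadpaths
Title: Mediation and Mendelian Randomization Pathways from Genetic Risk via
    Brain Morphology to Late-Onset Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing causal pathways from common genetic risk
    variants through regional brain morphology to late-onset Alzheimer's
    disease (LOAD). Implements family-history proxy-phenotype scoring with an
    age-weighted contribution capped at the population prevalence, APOE
    epsilon-4 allele counting from rs429358/rs7412 genotypes, genotype quality
    control (missingness and Hardy-Weinberg filters), hemisphere combination
    and global covariates for FreeSurfer-style regional measures, a
    variant-by-measure causal mediation grid with bootstrap inference on the
    indirect effect, Li-Ji effective-number-of-tests multiple-testing control,
    fixed-effect inverse-variance meta-analysis across cohorts, and one-sample
    bidirectional Mendelian randomization (inverse-variance weighted, weighted
    median, MR-Egger) with heterogeneity and instrument-strength diagnostics.
    A synthetic-cohort generator emulating the statistical structure of
    biobank and case-control neuroimaging-genetics cohorts makes the full
    pipeline testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
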