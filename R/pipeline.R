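#' Run the full pathway analysis
#'
#' Config-driven orchestration of the analysis stages in order: cohort input
#' (simulation or TSV files) -> genotype QC -> phenotype derivation ->
#' mediation grid with Li-Ji/FDR significance flags -> bidirectional MR on
#' the significant mediators (or an explicit measure list). All randomness
#' derives from the single seed in the config, so rerunning the same config
#' reproduces identical outputs.
#'
#' @param config Named list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{simulate}{List for synthetic input: `n_participants`,
#'       `cohort_style`, optional `apoe4_frequency`, optional `panel`
#'       (defaults to [synthetic_panel()]), optional `measure_names` to
#'       restrict the catalog, optional `outcome_params` /
#'       `mediator_residual_sd` / `missing_rate` forwarded to
#'       [cohort_config()]. Exactly one of `simulate` and `input` must be
#'       present.}
#'     \item{input}{List with `dir` holding `genotypes.tsv`,
#'       `phenotypes.tsv`, `params.json` as written by [write_cohort()].}
#'     \item{stages}{Logical toggles `qc`, `mediation`, `mr` (all default
#'       TRUE).}
#'     \item{bootstrap_reps}{Bootstrap resamples per mediation model
#'       (default 5000).}
#'     \item{fdr_q}{FDR level (default 0.05).}
#'     \item{seed}{Integer master seed (default 1).}
#'     \item{mr_measures}{Explicit measure names for MR; required when the
#'       mediation stage is off, otherwise defaults to the significant
#'       mediators.}
#'     \item{out_dir}{Optional directory; when given, `qc.tsv`,
#'       `mediation.tsv`, `mr.tsv` and `manifest.json` are written.}
#'   }
#' @return List with `qc`, `analysis` (derived table), `grid`, `mr`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    stop_validation("config must contain exactly one of 'simulate' or 'input'")
  stages <- utils::modifyList(list(qc = TRUE, mediation = TRUE, mr = TRUE),
                              config$stages %||% list())
  seed <- as.integer(config$seed %||% 1L)
  boot <- config$bootstrap_reps %||% 5000
  fdr_q <- config$fdr_q %||% 0.05

  if (has_sim) {
    sim <- config$simulate
    panel <- sim$panel %||% synthetic_panel(sim$apoe4_frequency %||% 0.15)
    measures <- measure_catalog()
    if (!is.null(sim$measure_names))
      measures <- measures[measures$name %in% sim$measure_names, , drop = FALSE]
    cfg <- cohort_config(sim$n_participants, seed = seed,
                         cohort_style = sim$cohort_style %||% "proxy",
                         mediator_residual_sd = sim$mediator_residual_sd %||% 1,
                         missing_rate = sim$missing_rate %||% 0,
                         outcome_params = sim$outcome_params %||% list())
    cohort <- simulate_cohort(cfg, panel, measures)
  } else {
    cohort <- read_cohort(config$input$dir)
    measures <- cohort$measures
    present <- vapply(measures$name, function(nm) {
      nm %in% names(cohort$phenotypes) ||
        paste0(nm, "__L") %in% names(cohort$phenotypes)
    }, logical(1))
    measures <- measures[present, , drop = FALSE]
    cohort$measures <- measures
  }
  variant_ids <- colnames(cohort$genotypes)

  qc <- NULL
  if (isTRUE(stages$qc)) {
    qc <- qc_variants(cohort$genotypes)
    variant_ids <- qc$variant_id[qc$passed]
    if (!length(variant_ids)) stop_validation("no variant passed QC")
  }

  analysis <- derive_analysis_data(cohort)

  grid <- NULL
  if (isTRUE(stages$mediation)) {
    grid <- run_grid(analysis, variant_ids, measures,
                     bootstrap_reps = boot, seed = seed + 1000L, q = fdr_q)
  }

  mr <- NULL
  if (isTRUE(stages$mr)) {
    if (!is.null(config$mr_measures)) {
      mr_measures <- measures[measures$name %in% config$mr_measures, , drop = FALSE]
    } else if (!is.null(grid)) {
      sig <- grid[grid$significant & !is.na(grid$significant), ]
      keys <- unique(paste0(sig$region, "__", sig$measure_type))
      mr_measures <- measures[measures$name %in% keys, , drop = FALSE]
    } else {
      stop_validation(paste("MR stage needs an explicit 'mr_measures' list",
                            "when the mediation stage is off"))
    }
    mr <- if (nrow(mr_measures))
      run_bidirectional(analysis, mr_measures, variant_ids,
                        seed = seed + 2000L, q = fdr_q)
    else NULL
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("loadpaths")),
    seed = seed, bootstrap_reps = boot, fdr_q = fdr_q,
    cohort_style = cohort$config$cohort_style,
    n_participants = cohort$config$n_participants,
    n_variants = length(variant_ids),
    n_measures = nrow(measures),
    n_models = if (!is.null(grid)) nrow(grid) else 0L,
    m_eff = if (!is.null(grid)) attr(grid, "m_eff") else NULL,
    stages = stages
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f)
      utils::write.table(df, file.path(config$out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "")
    if (!is.null(qc)) wt(qc, "qc.tsv")
    if (!is.null(grid)) wt(as.data.frame(grid), "mediation.tsv")
    if (!is.null(mr)) wt(as.data.frame(mr), "mr.tsv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(qc = qc, analysis = analysis, grid = grid, mr = mr, manifest = manifest)
}

## Read a run config from YAML (if the yaml package is available) or JSON.
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_validation("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
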