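#' Cortical region catalog
#'
#' The 34 cortical regions of the Desikan-Killiany parcellation, as produced
#' by FreeSurfer for each hemisphere. Surface area and mean thickness are
#' analysed for every cortical region.
#'
#' @return Character vector of 34 region names (snake_case).
#' @export
cortical_regions <- function() {
  c("bankssts", "caudal_anterior_cingulate", "caudal_middle_frontal",
    "cuneus", "entorhinal", "frontal_pole", "fusiform", "inferior_parietal",
    "inferior_temporal", "insula", "isthmus_cingulate", "lateral_occipital",
    "lateral_orbitofrontal", "lingual", "medial_orbitofrontal",
    "middle_temporal", "paracentral", "parahippocampal", "pars_opercularis",
    "pars_orbitalis", "pars_triangularis", "pericalcarine", "postcentral",
    "posterior_cingulate", "precentral", "precuneus",
    "rostral_anterior_cingulate", "rostral_middle_frontal", "superior_frontal",
    "superior_parietal", "superior_temporal", "supramarginal",
    "temporal_pole", "transverse_temporal")
}

#' Non-cortical volume catalog
#'
#' The 25 non-cortical structures whose volumes enter the analysis,
#' following the FreeSurfer subcortical segmentation. Structures present in
#' both hemispheres carry `lateral = TRUE` and are stored as left/right
#' columns; midline structures carry a single column.
#'
#' @return data.frame with columns `region` and `lateral`.
#' @export
noncortical_regions <- function() {
  lateral <- c("lateral_ventricle", "inferior_lateral_ventricle",
               "cerebellum_white_matter", "cerebellum_cortex", "thalamus",
               "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
               "accumbens", "ventral_dc", "vessel", "choroid_plexus")
  midline <- c("third_ventricle", "fourth_ventricle", "brain_stem", "csf",
               "optic_chiasm", "cc_posterior", "cc_mid_posterior",
               "cc_central", "cc_mid_anterior", "cc_anterior", "wm_hypointensities")
  data.frame(region = c(lateral, midline),
             lateral = rep(c(TRUE, FALSE), c(length(lateral), length(midline))),
             stringsAsFactors = FALSE)
}

#' Brain-measure catalog
#'
#' The full set of region-by-measure-type combinations analysed in the
#' mediation grid: surface area and mean thickness for each of the 34
#' cortical regions plus volume for each of the 25 non-cortical structures,
#' 93 measures in total.
#'
#' @return data.frame with columns `region`, `measure_type`
#'   (`"area"`, `"thickness"` or `"volume"`) and `name`
#'   (`<region>__<measure_type>`), in fixed catalog order.
#' @export
measure_catalog <- function() {
  cort <- cortical_regions()
  noncort <- noncortical_regions()$region
  out <- rbind(
    data.frame(region = cort, measure_type = "area", stringsAsFactors = FALSE),
    data.frame(region = cort, measure_type = "thickness", stringsAsFactors = FALSE),
    data.frame(region = noncort, measure_type = "volume", stringsAsFactors = FALSE)
  )
  out$name <- paste0(out$region, "__", out$measure_type)
  out
}

#' Global covariate matched to a measure type
#'
#' Every mediation and MR model includes a global brain-size covariate chosen
#' by the type of the regional measure: total surface area for areas, global
#' mean thickness for thicknesses, and intracranial volume (ICV) for volumes.
#'
#' @param measure_type `"area"`, `"thickness"` or `"volume"`.
#' @return Name of the analysis-table column holding the global covariate.
#' @export
global_covariate_for <- function(measure_type) {
  switch(match.arg(measure_type, c("area", "thickness", "volume")),
         area = "total_area",
         thickness = "global_thickness",
         volume = "icv")
}

#' Synthetic default variant panel
#'
#' A panel of 11 genetic risk variants for simulation: ten lead SNPs and the
#' APOE epsilon-4 allele count. Only rs75627662 and rs7384878 are real lead
#' SNPs reported for LOAD risk loci; the remaining eight SNP identifiers and
#' all allele frequencies are synthetic placeholders, so the panel is suitable
#' for exercising the pipeline but carries no biological content.
#'
#' @param apoe4_frequency Haplotype frequency of epsilon-4 used for the APOE
#'   pseudo-variant (default 0.15, a typical European value).
#' @return List of [variant_spec()] objects, APOE4 last.
#' @export
synthetic_panel <- function(apoe4_frequency = 0.15) {
  ids <- c("rs75627662", "rs7384878", paste0("snp_synth_", sprintf("%02d", 3:10)))
  freqs <- c(0.20, 0.30, 0.10, 0.15, 0.25, 0.35, 0.40, 0.45, 0.05, 0.12)
  panel <- mapply(function(id, f) variant_spec(id, "C", f),
                  ids, freqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  panel[[length(panel) + 1L]] <- variant_spec("APOE4", "C", apoe4_frequency)
  panel
}
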