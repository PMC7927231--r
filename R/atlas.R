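#' Atlas region labels
#'
#' Region label sets for the two networks the pipeline supports: the
#' 68-node cortical parcellation (34 regions per hemisphere, cortical
#' thickness in mm, labels in the `aparcstats2table` dialect
#' `lh_<region>_thickness`) and the 19-node subcortical set (9 structures
#' per hemisphere plus the brain stem, volumes in mm^3, `asegstats2table`
#' labels).
#'
#' @param atlas `"desikan68"` or `"subcortical19"`.
#' @return Character vector of region labels in canonical order.
#' @examples
#' length(atlas_regions("desikan68"))     # 68
#' length(atlas_regions("subcortical19")) # 19
#' @export
atlas_regions <- function(atlas = c("desikan68", "subcortical19")) {
  atlas <- match.arg(atlas)
  if (atlas == "desikan68") {
    base <- c(
      "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
      "cuneus", "entorhinal", "frontalpole", "fusiform",
      "inferiorparietal", "inferiortemporal", "insula",
      "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
      "lingual", "medialorbitofrontal", "middletemporal", "paracentral",
      "parahippocampal", "parsopercularis", "parsorbitalis",
      "parstriangularis", "pericalcarine", "postcentral",
      "posteriorcingulate", "precentral", "precuneus",
      "rostralanteriorcingulate", "rostralmiddlefrontal",
      "superiorfrontal", "superiorparietal", "superiortemporal",
      "supramarginal", "temporalpole", "transversetemporal")
    c(paste0("lh_", base, "_thickness"), paste0("rh_", base, "_thickness"))
  } else {
    base <- c("Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
              "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC",
              "Cerebellum-Cortex")
    c(paste0("Left-", base), paste0("Right-", base), "Brain-Stem")
  }
}

atlas_for_n <- function(n_regions) {
  if (n_regions == 68L) "desikan68"
  else if (n_regions == 19L) "subcortical19"
  else NA_character_
}

#' Default density grid
#'
#' Edge densities 0.10 to 0.50 in steps of 0.05: the low end sits just
#' above the fragmentation-prone regime for 68-node covariance networks,
#' the high end approaches the density at which binary topology becomes
#' uninformative.
#'
#' @return Numeric vector of nine densities.
#' @export
default_densities <- function() seq(0.10, 0.50, by = 0.05)

#' Names of the supported network measures
#'
#' @return Character vector of metric names usable wherever a `metrics`
#'   argument is accepted.
#' @export
metric_names <- function() {
  c("modularity", "transitivity", "assortativity", "clustering",
    "node_betweenness", "edge_betweenness", "degree_mean")
}
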