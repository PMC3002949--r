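#' Pipeline configuration
#'
#' Collects every tunable knob of the map-construction pipeline in one
#' validated list. Defaults reproduce the reference procedure: any >=1 bp
#' overlap links intervals, merged CNVs take the outer (union) span of
#' their supporting calls, a discordant call is rescued if it retains a
#' concordant partner, and a CNVR needs CNVs from at least two distinct
#' individuals.
#'
#' @param overlap_mode `"any_bp"` (default) or `"reciprocal"`. Under
#'   `"reciprocal"`, two intervals only count as overlapping when the
#'   intersection covers at least `reciprocal` of each interval's length.
#' @param reciprocal Reciprocal-overlap fraction in `(0, 1]`; only used
#'   when `overlap_mode = "reciprocal"`.
#' @param merge_span `"union"` (outer span of all supporting calls,
#'   default) or `"intersection"` (intersection of the two callers' spans
#'   within a merge group).
#' @param discordance_policy `"partner_rescue"` (default: a call is only
#'   removed as discordant when *all* its cross-caller partners disagree in
#'   direction) or `"remove_both"` (both members of any direction-discordant
#'   pair are removed outright).
#' @param min_individuals Minimum number of distinct individuals whose CNVs
#'   must overlap to form a CNVR in a population map (default 2).
#' @param direction_mode `"direction_agnostic"` (default: gains and losses
#'   cluster into one region, with per-direction member counts retained) or
#'   `"direction_stratified"` (separate gain and loss CNVRs).
#' @param cp_span `"union"` or `"intersection"` span for cross-population
#'   CNVRs.
#' @param exclusion_threshold Individuals with more than this many
#'   caller-reported CNVs are flagged and excluded from population
#'   statistics (default 500; such counts indicate caller
#'   over-fragmentation or misclassification).
#' @param genome_build Genome-build tag carried by maps and checked when
#'   maps or catalogs are compared (default `"hg18"`).
#' @return A list of class `cnvr_config`.
#' @export
cnvr_config <- function(overlap_mode = c("any_bp", "reciprocal"),
                        reciprocal = 0.5,
                        merge_span = c("union", "intersection"),
                        discordance_policy = c("partner_rescue", "remove_both"),
                        min_individuals = 2L,
                        direction_mode = c("direction_agnostic", "direction_stratified"),
                        cp_span = c("union", "intersection"),
                        exclusion_threshold = 500L,
                        genome_build = "hg18") {
  cfg <- list(
    overlap_mode = match.arg(overlap_mode),
    reciprocal = reciprocal,
    merge_span = match.arg(merge_span),
    discordance_policy = match.arg(discordance_policy),
    min_individuals = as.integer(min_individuals),
    direction_mode = match.arg(direction_mode),
    cp_span = match.arg(cp_span),
    exclusion_threshold = as.integer(exclusion_threshold),
    genome_build = as.character(genome_build)
  )
  if (cfg$min_individuals < 2L)
    stop("min_individuals must be >= 2: a CNVR requires CNVs from at least two individuals")
  if (cfg$overlap_mode == "reciprocal" &&
      (cfg$reciprocal <= 0 || cfg$reciprocal > 1))
    stop("reciprocal fraction must be in (0, 1]")
  structure(cfg, class = "cnvr_config")
}

# Effective reciprocal fraction: 0 means plain >=1 bp overlap.
.cfg_reciprocal <- function(config) {
  if (config$overlap_mode == "reciprocal") config$reciprocal else 0
}

#' @export
print.cnvr_config <- function(x, ...) {
  cat("CNVR pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, as.character(x[[k]])))
  invisible(x)
}
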