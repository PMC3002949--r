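# End-to-end orchestration: read -> congruency merge -> population maps ->
# cross-population map -> gene screening -> catalog comparison -> population
# statistics, with a manifest of conservation counters at every stage.

#' Run the full CNVR map-construction pipeline
#'
#' Executes every stage on in-memory call tables: per-individual
#' congruency merge for each population, population CNVR maps, the
#' cross-population map, gene screening and partition (when gene models
#' are supplied), catalog comparison (when a catalog is supplied), and
#' population-difference statistics. Rerunning with identical inputs and
#' configuration reproduces identical outputs; the manifest records the
#' configuration and every stage's conservation counters.
#'
#' @param populations Named list (one entry per population) of lists with
#'   elements `A` and `B`: that population's call tables per caller. Call
#'   tables may also be single data.frames carrying a `caller_id` column.
#' @param genes Optional gene feature table (see [read_features()]).
#' @param catalog Optional external interval catalog.
#' @param config A [cnvr_config()].
#' @param autosome_lengths Named chromosome lengths for genome-fraction
#'   computation (default hg18 autosomes).
#' @param out_dir Optional output directory; when given, maps are written
#'   as BED tracks and TSV tables, merged calls and summaries as TSV, and
#'   the manifest as JSON.
#' @return list of class `cnvr_pipeline_result`: `merged` (per
#'   population), `merge_reports`, `maps` (population maps plus `CP` when
#'   two populations are present), `gene_hits`, `gene_partition`,
#'   `catalog_reports`, `summaries`, `stats`, `manifest`.
#' @export
run_pipeline <- function(populations, genes = NULL, catalog = NULL,
                         config = cnvr_config(),
                         autosome_lengths = hg18_autosome_lengths(),
                         out_dir = NULL) {
  if (is.null(names(populations)) || any(!nzchar(names(populations))))
    stop("populations must be a named list")
  pop_labels <- names(populations)

  # stage 1: congruency merge per population
  merged <- list(); merge_reports <- list()
  for (pop in pop_labels) {
    calls <- .pop_calls(populations[[pop]])
    res <- merge_population(calls, pop, config)
    merged[[pop]] <- res$merged
    merge_reports[[pop]] <- res$report
  }

  # stage 2: population maps + cross-population map
  maps <- list()
  for (pop in pop_labels)
    maps[[pop]] <- build_population_map(merged[[pop]], pop, config,
                                        autosome_lengths)
  if (length(pop_labels) == 2L)
    maps$CP <- build_cross_population_map(maps[[pop_labels[1]]],
                                          maps[[pop_labels[2]]], config)

  # stage 3: annotation
  gene_hits <- NULL; gene_partition <- NULL
  if (!is.null(genes)) {
    gene_hits <- lapply(maps, genes_overlapping_map, genes = genes)
    if (length(pop_labels) == 2L)
      gene_partition <- partition_genes(gene_hits[[pop_labels[1]]],
                                        gene_hits[[pop_labels[2]]])
  }

  # stage 4: catalog comparison
  catalog_reports <- NULL
  if (!is.null(catalog))
    catalog_reports <- lapply(maps, function(m)
      catalog_vs_map(catalog, m, config, catalog_build = m$genome_build))

  # stage 5: population statistics (exclusion on caller-reported counts)
  summaries <- list(); stats_results <- list()
  for (pop in pop_labels) {
    calls <- .pop_calls(populations[[pop]])
    for (caller in c("A", "B")) {
      sub <- calls[calls$caller_id == caller, , drop = FALSE]
      summaries[[paste(pop, caller, sep = "_")]] <-
        summarize_individuals(sub, pop, config$exclusion_threshold)
    }
    summaries[[paste(pop, "merged", sep = "_")]] <-
      summarize_individuals(merged[[pop]], pop, config$exclusion_threshold)
  }
  if (length(pop_labels) == 2L) {
    for (src in c("A", "B", "merged")) {
      sa <- summaries[[paste(pop_labels[1], src, sep = "_")]]
      sb <- summaries[[paste(pop_labels[2], src, sep = "_")]]
      if (src == "merged") {
        # exclusion is a caller phenomenon: propagate raw-count flags
        excl1 <- .excluded_ids(summaries, pop_labels[1])
        excl2 <- .excluded_ids(summaries, pop_labels[2])
        sa$excluded <- sa$excluded | sa$individual_id %in% excl1
        sb$excluded <- sb$excluded | sb$individual_id %in% excl2
      }
      for (metric in c("n_cnvs", "mean_length")) {
        ok <- sum(!sa$excluded & !is.na(sa[[metric]])) >= 3 &&
          sum(!sb$excluded & !is.na(sb[[metric]])) >= 3
        if (ok)
          stats_results[[paste(src, metric, sep = "_")]] <-
            compare_populations(sa, sb, metric)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cnvrmap")),
    config = unclass(config),
    populations = pop_labels,
    counters = lapply(merge_reports, `[[`, "totals"),
    n_cnvrs = lapply(maps, function(m) nrow(m$cnvrs)),
    genome_fraction = lapply(maps, genome_fraction))

  result <- structure(list(merged = merged, merge_reports = merge_reports,
                           maps = maps, gene_hits = gene_hits,
                           gene_partition = gene_partition,
                           catalog_reports = catalog_reports,
                           summaries = summaries, stats = stats_results,
                           manifest = manifest),
                      class = "cnvr_pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

# Normalize one population's input: either a single call table with a
# caller_id column, or list(A = ..., B = ...).
.pop_calls <- function(x) {
  if (is.data.frame(x)) {
    if (!"caller_id" %in% names(x)) stop("call table needs a caller_id column")
    return(x)
  }
  stopifnot(all(c("A", "B") %in% names(x)))
  a <- x$A; b <- x$B
  if (!"caller_id" %in% names(a)) a$caller_id <- rep("A", nrow(a))
  if (!"caller_id" %in% names(b)) b$caller_id <- rep("B", nrow(b))
  cols <- union(names(a), names(b))
  for (cn in setdiff(cols, names(a))) a[[cn]] <- NA
  for (cn in setdiff(cols, names(b))) b[[cn]] <- NA
  rbind(a[cols], b[cols])
}

.excluded_ids <- function(summaries, pop) {
  unique(c(
    summaries[[paste(pop, "A", sep = "_")]]$individual_id[
      summaries[[paste(pop, "A", sep = "_")]]$excluded],
    summaries[[paste(pop, "B", sep = "_")]]$individual_id[
      summaries[[paste(pop, "B", sep = "_")]]$excluded]))
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (label in names(result$maps)) {
    write_map_bed(result$maps[[label]],
                  file.path(out_dir, sprintf("map_%s.bed", label)))
    write_cnvr_table(result$maps[[label]],
                     file.path(out_dir, sprintf("map_%s.tsv", label)))
  }
  for (pop in names(result$merged))
    write_merged_table(result$merged[[pop]],
                       file.path(out_dir, sprintf("merged_%s.tsv", pop)))
  for (key in names(result$summaries))
    utils::write.table(result$summaries[[key]],
                       file.path(out_dir, sprintf("summary_%s.tsv", key)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(result$stats)) {
    st <- do.call(rbind, lapply(names(result$stats), function(k) {
      x <- result$stats[[k]]
      data.frame(comparison = k, metric = x$metric,
                 group1 = x$labels[1], group2 = x$labels[2],
                 n1 = x$n[1], n2 = x$n[2],
                 median1 = x$medians[1], median2 = x$medians[2],
                 shapiro_p1 = x$shapiro_p[1], shapiro_p2 = x$shapiro_p[2],
                 U = x$statistic, p_value = x$p_value)
    }))
    utils::write.table(st, file.path(out_dir, "population_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.cnvr_pipeline_result <- function(x, ...) {
  cat("CNVR pipeline result\n")
  for (pop in names(x$merged))
    cat(sprintf("  %s: %d merged CNVs -> %d CNVRs\n", pop,
                nrow(x$merged[[pop]]), nrow(x$maps[[pop]]$cnvrs)))
  if (!is.null(x$maps$CP))
    cat(sprintf("  CP: %d cross-population CNVRs (%.3f%% of genome)\n",
                nrow(x$maps$CP$cnvrs), 100 * genome_fraction(x$maps$CP)))
  invisible(x)
}

#' Generate a synthetic study and run the full pipeline on it
#'
#' Convenience wrapper: builds the ground truth for a scenario, generates
#' the call set, runs [run_pipeline()] on it, and scores the resulting
#' maps against the planted loci.
#'
#' @param scenario Scenario name passed to [synthetic_truth()].
#' @param seed Integer seed.
#' @param config A [cnvr_config()].
#' @param out_dir Optional output directory for pipeline files.
#' @param ... Parameter overrides passed to [synthetic_truth()].
#' @return list: `data` (the generated set), `result` (pipeline result),
#'   `score` (recovery report from [score_against_truth()]).
#' @export
run_synthetic_pipeline <- function(scenario = "default", seed = 1L,
                                   config = cnvr_config(genome_build = "toy1"),
                                   out_dir = NULL, ...) {
  truth <- synthetic_truth(seed = seed, scenario = scenario, ...)
  data <- generate_synthetic_data(truth)
  pops <- lapply(truth$populations, function(pop)
    data$calls[data$calls$population == pop, , drop = FALSE])
  names(pops) <- truth$populations
  result <- run_pipeline(pops, genes = data$genes, catalog = data$catalog,
                         config = config, autosome_lengths = truth$genome,
                         out_dir = out_dir)
  score <- score_against_truth(result$maps, data)
  list(data = data, result = result, score = score)
}
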