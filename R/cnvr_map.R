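# CNVR map construction: single-linkage clustering of merged CNVs across
# individuals, population maps, the cross-population map, and summaries.

.new_cnvr_map <- function(label, genome_build, cnvrs, members,
                          autosome_lengths, check_overlap = TRUE) {
  if (check_overlap && nrow(cnvrs) > 1L) {
    # within a direction-agnostic map CNVRs must be pairwise disjoint
    cl <- .cluster_intervals(cnvrs)
    if (anyDuplicated(cl))
      stop("internal error: overlapping CNVRs within one map")
  }
  structure(list(label = label, genome_build = genome_build,
                 cnvrs = cnvrs, members = members,
                 autosome_lengths = autosome_lengths),
            class = "cnvr_map")
}

.empty_cnvr_frame <- function(pops = character(0)) {
  df <- data.frame(cnvr_id = character(0), chrom = character(0),
                   start = integer(0), end = integer(0), length = integer(0),
                   n_individuals = integer(0), n_loss = integer(0),
                   n_gain = integer(0), stringsAsFactors = FALSE)
  for (p in pops) df[[paste0("n_", p)]] <- integer(0)
  df
}

# Build CNVR rows from a member table with a precomputed cluster id.
.cnvrs_from_clusters <- function(members, cluster, label, pops) {
  sp <- split(seq_len(nrow(members)), cluster)
  rep_idx <- vapply(sp, `[`, 1L, 1L)
  s <- vapply(sp, function(ii) min(members$start[ii]), members$start[1])
  e <- vapply(sp, function(ii) max(members$end[ii]), members$end[1])
  r <- data.frame(
    cnvr_id = NA_character_, chrom = members$chrom[rep_idx],
    start = s, end = e, length = as.integer(e - s + 1),
    n_individuals = vapply(sp, function(ii)
      length(unique(members$individual_id[ii])), 1L),
    n_loss = vapply(sp, function(ii)
      sum(members$direction[ii] == "loss"), 1L),
    n_gain = vapply(sp, function(ii)
      sum(members$direction[ii] == "gain"), 1L),
    stringsAsFactors = FALSE)
  for (p in pops)
    r[[paste0("n_", p)]] <- vapply(sp, function(ii)
      length(unique(members$individual_id[ii][members$population[ii] == p])), 1L)
  r$members <- I(unname(sp))
  r
}

#' Build a population-specific CNVR map
#'
#' Single-linkage clusters of overlapping merged CNVs across the
#' individuals of one population become CNVRs. A cluster qualifies only
#' when it contains CNVs from at least `min_individuals` distinct
#' individuals (default 2); singletons never form a CNVR. Frequency is
#' counted as distinct individuals, not raw events, so one fragmented
#' individual cannot satisfy the threshold alone.
#'
#' @param merged Merged-CNV table from [merge_population()] (a
#'   `population` column is added from `label` if absent).
#' @param label Map label, e.g. `"SW"` or `"RW"`.
#' @param config A [cnvr_config()]: `min_individuals` and `direction_mode`
#'   (`"direction_agnostic"` default: gains and losses cluster together,
#'   with per-direction counts retained; `"direction_stratified"`:
#'   separate gain and loss CNVRs).
#' @param autosome_lengths Named chromosome-length vector for
#'   genome-fraction computation; defaults to [hg18_autosome_lengths()].
#' @return A `cnvr_map` object: list with `label`, `genome_build`,
#'   `cnvrs` (sorted, pairwise non-overlapping in the default mode),
#'   `members`, `autosome_lengths`.
#' @export
build_population_map <- function(merged, label, config = cnvr_config(),
                                 autosome_lengths = hg18_autosome_lengths()) {
  .validate_calls(merged, "merged")
  if (!"population" %in% names(merged))
    merged$population <- rep(label, nrow(merged))
  pops <- unique(merged$population)
  if (nrow(merged) == 0L)
    return(.new_cnvr_map(label, config$genome_build, .empty_cnvr_frame(pops),
                         merged, autosome_lengths))
  if (config$direction_mode == "direction_stratified") {
    cluster <- paste(merged$direction,
                     ave(seq_len(nrow(merged)), merged$direction,
                         FUN = function(ii) .cluster_intervals(merged[ii, , drop = FALSE])),
                     sep = "|")
  } else {
    cluster <- .cluster_intervals(merged)
  }
  cnvrs <- .cnvrs_from_clusters(merged, cluster, label, pops)
  cnvrs <- cnvrs[cnvrs$n_individuals >= config$min_individuals, , drop = FALSE]
  member_rows <- cnvrs$members
  cnvrs$members <- NULL
  ord <- .interval_order(cnvrs)
  cnvrs <- cnvrs[ord, , drop = FALSE]
  member_rows <- member_rows[ord]
  cnvrs$cnvr_id <- sprintf("%s_CNVR_%05d", label, seq_len(nrow(cnvrs)))
  members <- if (nrow(cnvrs)) {
    mm <- merged[unlist(member_rows), , drop = FALSE]
    mm$cnvr_id <- rep(cnvrs$cnvr_id, lengths(member_rows))
    rownames(mm) <- NULL
    mm
  } else cbind(merged[0, , drop = FALSE], cnvr_id = character(0))
  rownames(cnvrs) <- NULL
  .new_cnvr_map(label, config$genome_build, cnvrs, members, autosome_lengths,
                check_overlap = config$direction_mode == "direction_agnostic")
}

#' Build the cross-population CNVR map
#'
#' CNVRs common to both input maps: single-linkage clusters over the
#' pooled CNVRs of the two maps, keeping only clusters with contributions
#' from each map. Because each input CNVR already carries CNVs from at
#' least two individuals, every cross-population CNVR is supported by at
#' least 2 x 2 CNV events. Coordinates are by default the union span of
#' the linked cluster; `cp_span = "intersection"` intersects the two
#' maps' spans instead.
#'
#' @param map_a,map_b Two `cnvr_map` objects sharing a genome build.
#' @param config A [cnvr_config()] (`cp_span`).
#' @param label Label for the result (default `"CP"`).
#' @return A `cnvr_map`; `population_counts` columns (`n_<pop>`) carry the
#'   distinct-individual counts of both populations.
#' @export
build_cross_population_map <- function(map_a, map_b, config = cnvr_config(),
                                       label = "CP") {
  stopifnot(inherits(map_a, "cnvr_map"), inherits(map_b, "cnvr_map"))
  if (!identical(map_a$genome_build, map_b$genome_build))
    stop(sprintf("genome build mismatch: %s vs %s",
                 map_a$genome_build, map_b$genome_build))
  pooled <- rbind(
    cbind(map_a$cnvrs[c("cnvr_id", "chrom", "start", "end")], source = "a"),
    cbind(map_b$cnvrs[c("cnvr_id", "chrom", "start", "end")], source = "b"))
  pops <- unique(c(map_a$members$population, map_b$members$population,
                   map_a$label, map_b$label))
  all_members <- rbind(map_a$members, map_b$members)
  if (nrow(pooled) == 0L)
    return(.new_cnvr_map(label, map_a$genome_build, .empty_cnvr_frame(pops),
                         all_members[0, , drop = FALSE], map_a$autosome_lengths))
  cl <- .cluster_intervals(pooled)
  keep_cl <- names(which(tapply(pooled$source, cl, function(s)
    length(unique(s)) == 2L)))
  rows <- lapply(keep_cl, function(k) {
    ii <- which(cl == as.integer(k))
    g <- pooled[ii, , drop = FALSE]
    mm <- all_members[all_members$cnvr_id %in% g$cnvr_id, , drop = FALSE]
    if (config$cp_span == "union") {
      s <- min(g$start); e <- max(g$end)
    } else {
      s <- max(min(g$start[g$source == "a"]), min(g$start[g$source == "b"]))
      e <- min(max(g$end[g$source == "a"]), max(g$end[g$source == "b"]))
    }
    r <- data.frame(cnvr_id = NA_character_, chrom = g$chrom[1],
                    start = s, end = e, length = e - s + 1L,
                    n_individuals = length(unique(mm$individual_id)),
                    n_loss = sum(mm$direction == "loss"),
                    n_gain = sum(mm$direction == "gain"),
                    stringsAsFactors = FALSE)
    for (p in pops)
      r[[paste0("n_", p)]] <-
        length(unique(mm$individual_id[mm$population == p]))
    r$member_ids <- I(list(mm))
    r
  })
  cnvrs <- do.call(rbind, rows)
  if (is.null(cnvrs)) cnvrs <- .empty_cnvr_frame(pops)
  member_tabs <- cnvrs$member_ids
  cnvrs$member_ids <- NULL
  ord <- .interval_order(cnvrs)
  cnvrs <- cnvrs[ord, , drop = FALSE]
  member_tabs <- member_tabs[ord]
  cnvrs$cnvr_id <- sprintf("%s_CNVR_%05d", label, seq_len(nrow(cnvrs)))
  members <- if (nrow(cnvrs)) {
    mm <- do.call(rbind, member_tabs)
    mm$cnvr_id <- rep(cnvrs$cnvr_id, vapply(member_tabs, nrow, 1L))
    rownames(mm) <- NULL
    mm
  } else all_members[0, , drop = FALSE]
  rownames(cnvrs) <- NULL
  # union spans of "common" clusters can themselves touch; do not enforce
  # disjointness under intersection spans
  .new_cnvr_map(label, map_a$genome_build, cnvrs, members,
                map_a$autosome_lengths,
                check_overlap = config$cp_span == "union")
}

#' Wrap an interval table as a CNVR map
#'
#' Builds a memberless `cnvr_map` from a plain interval table (e.g. an
#' external CNVR catalog read with [read_features()]), for use with the
#' map-comparison operations. No non-overlap or frequency constraints are
#' enforced on external maps.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param label Map label.
#' @param genome_build Build tag (default `"hg18"`).
#' @param autosome_lengths Chromosome lengths (default hg18).
#' @return A `cnvr_map` with `n_individuals`, `n_loss`, `n_gain` set to `NA`.
#' @export
as_cnvr_map <- function(intervals, label, genome_build = "hg18",
                        autosome_lengths = hg18_autosome_lengths()) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  n <- nrow(intervals)
  cnvrs <- data.frame(
    cnvr_id = if ("name" %in% names(intervals)) as.character(intervals$name)
      else sprintf("%s_CNVR_%05d", label, seq_len(n)),
    chrom = normalize_chrom(intervals$chrom),
    start = as.integer(intervals$start), end = as.integer(intervals$end),
    length = as.integer(intervals$end - intervals$start + 1),
    n_individuals = NA_integer_, n_loss = NA_integer_, n_gain = NA_integer_,
    stringsAsFactors = FALSE)
  cnvrs <- cnvrs[.interval_order(cnvrs), , drop = FALSE]
  rownames(cnvrs) <- NULL
  .new_cnvr_map(label, genome_build, cnvrs, members = NULL,
                autosome_lengths = autosome_lengths, check_overlap = FALSE)
}

#' Fraction of the haploid autosomal genome covered by a map
#'
#' Sum of CNVR lengths divided by the sum of autosome lengths. CNVRs
#' within a map are non-overlapping, so the sum is the covered territory.
#'
#' @param map A `cnvr_map`.
#' @return A fraction in `[0, 1]`.
#' @export
genome_fraction <- function(map) {
  stopifnot(inherits(map, "cnvr_map"))
  if (nrow(map$cnvrs) == 0L) return(0)
  missing_chr <- setdiff(unique(map$cnvrs$chrom), names(map$autosome_lengths))
  if (length(missing_chr))
    stop("no autosome length for chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  sum(as.numeric(map$cnvrs$length)) / sum(as.numeric(map$autosome_lengths))
}

#' Summarize a CNVR map
#'
#' Per-CNVR rows (length, frequency = distinct individuals, gain/loss
#' member counts) plus totals: CNVR count, median length, total member
#' events, and a frequency histogram — the ingredients of length/frequency
#' distribution plots.
#'
#' @param map A `cnvr_map`.
#' @return list with `per_cnvr`, `n_cnvrs`, `median_length`,
#'   `total_members`, `frequency_table`.
#' @export
map_summary <- function(map) {
  stopifnot(inherits(map, "cnvr_map"))
  cv <- map$cnvrs
  per <- cv[c("cnvr_id", "chrom", "start", "end", "length",
              "n_individuals", "n_loss", "n_gain")]
  list(per_cnvr = per,
       n_cnvrs = nrow(cv),
       median_length = if (nrow(cv)) stats::median(cv$length) else 0,
       total_members = if (nrow(cv)) sum(cv$n_loss + cv$n_gain) else 0L,
       frequency_table = table(cv$n_individuals))
}

#' @export
print.cnvr_map <- function(x, ...) {
  cat(sprintf("CNVR map '%s' (%s): %d CNVRs", x$label, x$genome_build,
              nrow(x$cnvrs)))
  if (nrow(x$cnvrs))
    cat(sprintf(", median length %s bp",
                format(stats::median(x$cnvrs$length), big.mark = ",")))
  cat("\n")
  invisible(x)
}
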