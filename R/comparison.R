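# External-validation arithmetic: catalog records clustering in a map's
# CNVRs, map-vs-map overlapping regions, and per-individual cross-platform
# call concordance.

#' Compare an external interval catalog against a CNVR map
#'
#' Counts catalog records (e.g. single CNV entries of a genomic-variants
#' database, or segmental duplications) that overlap at least one CNVR of
#' the map, the CNVRs hit, and the CNVRs overlapping no catalog record
#' (the map's novel regions). Catalog records on sex chromosomes are
#' dropped with a count; the comparison is restricted to autosomes.
#'
#' @param catalog Feature table (`chrom`, `start`, `end`, optionally
#'   `name`), e.g. from [read_features()].
#' @param map A `cnvr_map`.
#' @param config A [cnvr_config()]; overlap is >=1 bp by default, with the
#'   reciprocal-overlap knob available for sensitivity analyses.
#' @param catalog_build Optional build tag of the catalog; a mismatch with
#'   the map's build is an error unless `ignore_build = TRUE`.
#' @param ignore_build Override the build check.
#' @param label Catalog label carried into the report.
#' @return list of class `catalog_overlap_report`: `label`,
#'   `n_catalog_records` (autosomal), `n_dropped_nonautosomal`,
#'   `n_records_in_map`, `n_cnvrs_hit`, `n_cnvrs_novel`, `novel_cnvrs`
#'   (data.frame of CNVRs overlapping zero records).
#' @export
catalog_vs_map <- function(catalog, map, config = cnvr_config(),
                           catalog_build = NULL, ignore_build = FALSE,
                           label = "catalog") {
  stopifnot(inherits(map, "cnvr_map"))
  if (!is.null(catalog_build) && !ignore_build &&
      !identical(catalog_build, map$genome_build))
    stop(sprintf("genome build mismatch: catalog %s vs map %s (set ignore_build = TRUE to override)",
                 catalog_build, map$genome_build))
  catalog$chrom <- normalize_chrom(catalog$chrom)
  auto <- catalog$chrom %in% autosome_names()
  dropped <- sum(!auto)
  catalog <- catalog[auto, , drop = FALSE]
  pr <- .overlap_pairs(catalog, map$cnvrs, reciprocal = .cfg_reciprocal(config))
  hit_cnvrs <- unique(pr$j)
  novel <- map$cnvrs[!seq_len(nrow(map$cnvrs)) %in% hit_cnvrs, , drop = FALSE]
  out <- list(label = label,
              n_catalog_records = nrow(catalog),
              n_dropped_nonautosomal = dropped,
              n_records_in_map = length(unique(pr$i)),
              n_cnvrs_hit = length(hit_cnvrs),
              n_cnvrs_novel = nrow(novel),
              novel_cnvrs = novel)
  stopifnot(out$n_cnvrs_hit + out$n_cnvrs_novel == nrow(map$cnvrs))
  class(out) <- "catalog_overlap_report"
  out
}

#' @export
print.catalog_overlap_report <- function(x, ...) {
  cat(sprintf("catalog '%s' vs map: %d/%d records in map; %d CNVRs hit, %d novel\n",
              x$label, x$n_records_in_map, x$n_catalog_records,
              x$n_cnvrs_hit, x$n_cnvrs_novel))
  invisible(x)
}

#' Count overlapping regions between two CNVR maps
#'
#' Reports, in both directions, how many CNVRs of one map overlap at
#' least one CNVR of the other (the counts differ in general, which is
#' why both are returned).
#'
#' @param map_a,map_b Two `cnvr_map` objects sharing a genome build.
#' @param config A [cnvr_config()].
#' @param ignore_build Override the build check.
#' @return list: `n_a_hit`, `n_b_hit`, `a_hit_ids`, `b_hit_ids`.
#' @export
map_vs_map <- function(map_a, map_b, config = cnvr_config(),
                       ignore_build = FALSE) {
  stopifnot(inherits(map_a, "cnvr_map"), inherits(map_b, "cnvr_map"))
  if (!ignore_build && !identical(map_a$genome_build, map_b$genome_build))
    stop(sprintf("genome build mismatch: %s vs %s",
                 map_a$genome_build, map_b$genome_build))
  pr <- .overlap_pairs(map_a$cnvrs, map_b$cnvrs,
                       reciprocal = .cfg_reciprocal(config))
  list(n_a_hit = length(unique(pr$i)),
       n_b_hit = length(unique(pr$j)),
       a_hit_ids = map_a$cnvrs$cnvr_id[sort(unique(pr$i))],
       b_hit_ids = map_b$cnvrs$cnvr_id[sort(unique(pr$j))])
}

#' Per-individual cross-platform call concordance
#'
#' For individuals assayed on two platforms, counts how many platform-1
#' events were also detected in the *same individual* by platform 2: an
#' event is concordant iff it overlaps (>=1 bp, same chromosome, same
#' individual) a platform-2 event. Direction agreement is optional.
#'
#' @param calls_p1,calls_p2 Call tables (columns `individual_id`, `chrom`,
#'   `start`, `end`, `direction`) from the two platforms.
#' @param require_direction Also require equal direction (default FALSE).
#' @param config A [cnvr_config()].
#' @return list with `per_individual` (data.frame: `individual_id`,
#'   `n_calls_p1`, `n_calls_p2`, `n_concordant`) over the shared
#'   individuals, and `totals`. If the platforms share no individuals an
#'   empty report is returned with a warning.
#' @export
per_individual_concordance <- function(calls_p1, calls_p2,
                                       require_direction = FALSE,
                                       config = cnvr_config()) {
  .validate_calls(calls_p1, "calls_p1"); .validate_calls(calls_p2, "calls_p2")
  shared <- intersect(unique(calls_p1$individual_id),
                      unique(calls_p2$individual_id))
  if (length(shared) == 0L) {
    warning("platforms share no individuals")
    per <- data.frame(individual_id = character(0), n_calls_p1 = integer(0),
                      n_calls_p2 = integer(0), n_concordant = integer(0))
    return(list(per_individual = per,
                totals = list(n_calls_p1 = 0L, n_calls_p2 = 0L,
                              n_concordant = 0L)))
  }
  rows <- lapply(shared, function(ind) {
    p1 <- calls_p1[calls_p1$individual_id == ind, , drop = FALSE]
    p2 <- calls_p2[calls_p2$individual_id == ind, , drop = FALSE]
    pr <- .overlap_pairs(p1, p2, reciprocal = .cfg_reciprocal(config))
    if (require_direction && nrow(pr))
      pr <- pr[p1$direction[pr$i] == p2$direction[pr$j], , drop = FALSE]
    data.frame(individual_id = ind, n_calls_p1 = nrow(p1),
               n_calls_p2 = nrow(p2), n_concordant = length(unique(pr$i)),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  stopifnot(all(per$n_concordant <= pmin(per$n_calls_p1, per$n_calls_p2) |
                  per$n_concordant <= per$n_calls_p1))
  list(per_individual = per,
       totals = list(n_calls_p1 = sum(per$n_calls_p1),
                     n_calls_p2 = sum(per$n_calls_p2),
                     n_concordant = sum(per$n_concordant)))
}
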