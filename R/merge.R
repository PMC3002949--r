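# Two-caller congruency check and merge: per individual, keep only CNVs
# supported by both callers with equal direction of effect, and collapse
# each concordant overlapping group into one merged CNV.

.empty_merged <- function() {
  data.frame(individual_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), direction = character(0),
             n_support_a = integer(0), n_support_b = integer(0),
             support_a = character(0), support_b = character(0),
             stringsAsFactors = FALSE)
}

# Pre-merge within-caller overlapping calls per (chrom, direction).
# Callers emit segmentations, so overlaps within one caller and direction
# are a pathology; they are collapsed before cross-caller comparison.
# Returns list(calls, n_premerged) where n_premerged counts input calls
# absorbed into within-caller collapses (input rows - output rows).
.premerge_within_caller <- function(calls) {
  n <- nrow(calls)
  if (n <= 1L) return(list(calls = calls, n_premerged = 0L))
  keyed <- calls
  keyed$chrom <- paste(calls$chrom, calls$direction)
  cl <- .cluster_intervals(keyed)
  if (!anyDuplicated(cl)) return(list(calls = calls, n_premerged = 0L))
  sp <- split(seq_len(n), cl)
  out <- calls[vapply(sp, `[`, 1L, 1L), , drop = FALSE]
  out$start <- vapply(sp, function(ii) min(calls$start[ii]), calls$start[1])
  out$end <- vapply(sp, function(ii) max(calls$end[ii]), calls$end[1])
  if ("n_markers" %in% names(calls))
    out$n_markers <- vapply(sp, function(ii) {
      x <- calls$n_markers[ii]
      if (all(is.na(x))) NA_integer_ else as.integer(sum(x, na.rm = TRUE))
    }, NA_integer_)
  rownames(out) <- NULL
  list(calls = out, n_premerged = n - nrow(out))
}

#' Find cross-caller overlapping call pairs for one individual
#'
#' Returns every pair of calls, one from each caller, that lies on the
#' same chromosome and shares at least one base, regardless of direction.
#' Intervals sharing exactly one base overlap; book-ended intervals
#' (`end + 1 == start`) do not.
#'
#' @param calls_a,calls_b Call tables for one individual, one caller each.
#' @param config A [cnvr_config()]; under reciprocal overlap mode the pair
#'   must additionally satisfy the reciprocal fraction.
#' @return data.frame with row indices `a`, `b` into the two inputs and a
#'   logical `concordant` (equal direction).
#' @export
find_cross_caller_overlaps <- function(calls_a, calls_b, config = cnvr_config()) {
  .validate_calls(calls_a, "calls_a"); .validate_calls(calls_b, "calls_b")
  inds <- unique(c(calls_a$individual_id, calls_b$individual_id))
  if (length(inds) > 1L)
    stop("mixed individual_ids in cross-caller overlap input: ",
         paste(inds, collapse = ", "))
  pr <- .overlap_pairs(calls_a, calls_b, reciprocal = .cfg_reciprocal(config))
  data.frame(a = pr$i, b = pr$j,
             concordant = if (nrow(pr))
               calls_a$direction[pr$i] == calls_b$direction[pr$j] else logical(0))
}

#' Apply the direction-congruency filter to overlapping call pairs
#'
#' Pairs whose two calls disagree in direction of effect (loss vs. gain)
#' are removed. Under the default `partner_rescue` policy a call is
#' counted as discordant-removed only when *all* of its cross-caller
#' partners disagree; under `remove_both` every call participating in any
#' discordant pair is removed outright, and a surviving call whose only
#' concordant partners were themselves removed is counted as unsupported.
#' Calls overlapping nothing from the other caller are always counted as
#' unsupported-removed: a CNV not at least partially detected by the
#' second algorithm is discarded.
#'
#' @param pairs Output of [find_cross_caller_overlaps()].
#' @param calls_a,calls_b The same call tables the pairs index into.
#' @param config A [cnvr_config()] (`discordance_policy`).
#' @return list with `pairs` (surviving, all concordant), `keep_a`/`keep_b`
#'   (logical row masks of absorbed calls) and counters
#'   `n_discordant_removed`, `n_unsupported_removed`.
#' @export
apply_congruency_filter <- function(pairs, calls_a, calls_b,
                                    config = cnvr_config()) {
  na <- nrow(calls_a); nb <- nrow(calls_b)
  in_pair_a <- seq_len(na) %in% pairs$a
  in_pair_b <- seq_len(nb) %in% pairs$b
  conc <- pairs[pairs$concordant, , drop = FALSE]
  disc <- pairs[!pairs$concordant, , drop = FALSE]
  if (config$discordance_policy == "partner_rescue") {
    keep_a <- seq_len(na) %in% conc$a
    keep_b <- seq_len(nb) %in% conc$b
    surviving <- conc
  } else { # remove_both
    bad_a <- seq_len(na) %in% disc$a
    bad_b <- seq_len(nb) %in% disc$b
    surviving <- conc[!bad_a[conc$a] & !bad_b[conc$b], , drop = FALSE]
    keep_a <- seq_len(na) %in% surviving$a
    keep_b <- seq_len(nb) %in% surviving$b
  }
  # every call is exactly one of: absorbed, discordant-removed, unsupported
  if (config$discordance_policy == "partner_rescue") {
    disc_a <- in_pair_a & !keep_a
    disc_b <- in_pair_b & !keep_b
  } else {
    disc_a <- seq_len(na) %in% disc$a
    disc_b <- seq_len(nb) %in% disc$b
  }
  unsupported_a <- !in_pair_a | (!keep_a & !disc_a)
  unsupported_b <- !in_pair_b | (!keep_b & !disc_b)
  list(pairs = surviving, keep_a = keep_a, keep_b = keep_b,
       n_discordant_removed = sum(disc_a) + sum(disc_b),
       n_unsupported_removed = sum(unsupported_a) + sum(unsupported_b))
}

#' Merge direction-concordant, two-caller-supported calls into CNVs
#'
#' Connected components of the surviving pair graph (calls as nodes,
#' concordant overlapping pairs as edges) each become exactly one merged
#' CNV spanning, by default, the union (outer) extent of all supporting
#' calls. Because within-caller calls are non-overlapping per chromosome
#' and direction, the components coincide with single-linkage interval
#' clusters of the surviving calls per direction.
#'
#' @param filtered Output of [apply_congruency_filter()].
#' @param calls_a,calls_b The call tables the filter indexed into.
#' @param config A [cnvr_config()]; `merge_span = "intersection"` uses the
#'   intersection of the two callers' union spans within each component.
#' @return data.frame of merged CNVs (`individual_id`, `chrom`, `start`,
#'   `end`, `direction`, `n_support_a`, `n_support_b`, `support_a`,
#'   `support_b`).
#' @export
merge_concordant <- function(filtered, calls_a, calls_b,
                             config = cnvr_config()) {
  keep_a <- which(filtered$keep_a); keep_b <- which(filtered$keep_b)
  if (length(keep_a) + length(keep_b) == 0L) return(.empty_merged())
  surv <- rbind(
    cbind(calls_a[keep_a, c("individual_id", "chrom", "start", "end", "direction")],
          caller = "A", idx = keep_a),
    cbind(calls_b[keep_b, c("individual_id", "chrom", "start", "end", "direction")],
          caller = "B", idx = keep_b))
  rownames(surv) <- NULL
  keyed <- surv
  keyed$chrom <- paste(surv$chrom, surv$direction)
  cl <- .cluster_intervals(keyed)
  sp <- split(seq_len(nrow(surv)), cl)
  rep_idx <- vapply(sp, `[`, 1L, 1L)
  is_a <- surv$caller == "A"
  n_a <- vapply(sp, function(ii) sum(is_a[ii]), 1L)
  n_b <- lengths(sp) - n_a
  if (any(n_a == 0L) || any(n_b == 0L))
    stop("internal error: merge component lacks two-caller support")
  span <- if (config$merge_span == "union") {
    list(s = vapply(sp, function(ii) min(surv$start[ii]), surv$start[1]),
         e = vapply(sp, function(ii) max(surv$end[ii]), surv$end[1]))
  } else {
    list(s = vapply(sp, function(ii)
           max(min(surv$start[ii][is_a[ii]]), min(surv$start[ii][!is_a[ii]])),
           surv$start[1]),
         e = vapply(sp, function(ii)
           min(max(surv$end[ii][is_a[ii]]), max(surv$end[ii][!is_a[ii]])),
           surv$end[1]))
  }
  out <- data.frame(
    individual_id = surv$individual_id[rep_idx], chrom = surv$chrom[rep_idx],
    start = span$s, end = span$e, direction = surv$direction[rep_idx],
    n_support_a = n_a, n_support_b = n_b,
    support_a = vapply(sp, function(ii)
      paste0("A:", sort(surv$idx[ii][is_a[ii]]), collapse = ","), ""),
    support_b = vapply(sp, function(ii)
      paste0("B:", sort(surv$idx[ii][!is_a[ii]]), collapse = ","), ""),
    stringsAsFactors = FALSE)
  out <- out[.interval_order(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Congruency-merge one individual's two-caller calls
#'
#' Runs the full per-individual procedure: pre-merge within-caller
#' overlaps, find cross-caller overlapping pairs, filter for equal
#' direction of effect, and merge each concordant component into one CNV.
#'
#' @param calls_a,calls_b One individual's calls from caller A and B.
#' @param config A [cnvr_config()].
#' @return list with `merged` (see [merge_concordant()]) and `report`, a
#'   one-row data.frame of conservation counters satisfying
#'   `n_input_a + n_input_b = n_absorbed + n_discordant_removed +
#'   n_unsupported_removed` (inputs counted after within-caller
#'   pre-merging; `n_premerged_*` record collapsed raw calls).
#' @export
merge_individual <- function(calls_a, calls_b, config = cnvr_config()) {
  pa <- .premerge_within_caller(calls_a)
  pb <- .premerge_within_caller(calls_b)
  if (pa$n_premerged + pb$n_premerged > 0L)
    warning(sprintf("individual %s: %d within-caller overlapping call(s) pre-merged",
                    c(calls_a$individual_id, calls_b$individual_id)[1],
                    pa$n_premerged + pb$n_premerged))
  calls_a <- pa$calls; calls_b <- pb$calls
  pairs <- find_cross_caller_overlaps(calls_a, calls_b, config)
  filt <- apply_congruency_filter(pairs, calls_a, calls_b, config)
  merged <- merge_concordant(filt, calls_a, calls_b, config)
  ind <- unique(c(calls_a$individual_id, calls_b$individual_id))
  report <- data.frame(
    individual_id = if (length(ind)) ind[1] else NA_character_,
    n_input_a = nrow(calls_a), n_input_b = nrow(calls_b),
    n_premerged_a = pa$n_premerged, n_premerged_b = pb$n_premerged,
    n_merged = nrow(merged),
    n_absorbed = sum(filt$keep_a) + sum(filt$keep_b),
    n_discordant_removed = filt$n_discordant_removed,
    n_unsupported_removed = filt$n_unsupported_removed,
    stringsAsFactors = FALSE)
  stopifnot(report$n_input_a + report$n_input_b ==
              report$n_absorbed + report$n_discordant_removed +
              report$n_unsupported_removed)
  list(merged = merged, report = report)
}

#' Congruency-merge a whole population
#'
#' Applies [merge_individual()] to every individual in a population's
#' two-caller call set. Individuals present in only one caller's data get
#' all their calls counted unsupported, with a warning.
#'
#' @param calls Call table for one population containing both callers
#'   (column `caller_id` with values `"A"`/`"B"`).
#' @param population_label Label stored on the merged calls (e.g. `"SW"`).
#' @param config A [cnvr_config()].
#' @return list with `merged` (all individuals, extra column `population`)
#'   and `report`: list of `totals` (summed counters) and `per_individual`.
#' @export
merge_population <- function(calls, population_label, config = cnvr_config()) {
  .validate_calls(calls, "calls")
  if (!"caller_id" %in% names(calls)) stop("calls must carry a caller_id column")
  if (!all(calls$caller_id %in% c("A", "B")))
    stop("caller_id must be 'A' or 'B'")
  inds <- unique(calls$individual_id)
  one_caller <- vapply(inds, function(i)
    length(unique(calls$caller_id[calls$individual_id == i])) < 2L, logical(1))
  if (any(one_caller))
    warning(sprintf("%d individual(s) present in only one caller's data; all their calls are unsupported",
                    sum(one_caller)))
  merged_list <- vector("list", length(inds))
  report_list <- vector("list", length(inds))
  for (k in seq_along(inds)) {
    sub <- calls[calls$individual_id == inds[k], , drop = FALSE]
    res <- suppressWarnings(
      merge_individual(sub[sub$caller_id == "A", , drop = FALSE],
                       sub[sub$caller_id == "B", , drop = FALSE], config))
    merged_list[[k]] <- res$merged
    report_list[[k]] <- res$report
  }
  merged <- do.call(rbind, merged_list)
  if (is.null(merged) || nrow(merged) == 0L) merged <- .empty_merged()
  merged$population <- rep(population_label, nrow(merged))
  per_ind <- do.call(rbind, report_list)
  if (is.null(per_ind))
    per_ind <- data.frame(individual_id = character(0), n_input_a = integer(0),
                          n_input_b = integer(0), n_premerged_a = integer(0),
                          n_premerged_b = integer(0), n_merged = integer(0),
                          n_absorbed = integer(0),
                          n_discordant_removed = integer(0),
                          n_unsupported_removed = integer(0))
  rownames(per_ind) <- NULL
  totals <- as.list(colSums(per_ind[setdiff(names(per_ind), "individual_id")]))
  totals$population <- population_label
  stopifnot(totals$n_input_a + totals$n_input_b ==
              totals$n_absorbed + totals$n_discordant_removed +
              totals$n_unsupported_removed)
  list(merged = merged, report = list(totals = totals, per_individual = per_ind))
}
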