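#' Autosome lengths for the hg18 (NCBI36) assembly
#'
#' Chromosome lengths, in base pairs, for the 22 human autosomes of the
#' March 2006 assembly (NCBI36/hg18). Used as the default denominator when
#' computing the fraction of the haploid autosomal genome covered by a CNVR
#' map. Sex chromosomes are excluded throughout the package.
#'
#' @return Named numeric vector; names are chromosome names `"1".."22"`.
#' @export
#' @examples
#' sum(hg18_autosome_lengths()) # ~2.87 Gb of autosomal sequence
hg18_autosome_lengths <- function() {
  c(`1` = 247249719, `2` = 242951149, `3` = 199501827, `4` = 191273063,
    `5` = 180857866, `6` = 170899992, `7` = 158821424, `8` = 146274826,
    `9` = 140273252, `10` = 135374737, `11` = 134452384, `12` = 132349534,
    `13` = 114142980, `14` = 106368585, `15` = 100338915, `16` = 88827254,
    `17` = 78774742, `18` = 76117153, `19` = 63811651, `20` = 62435964,
    `21` = 46944323, `22` = 49691432)
}

autosome_names <- function() as.character(1:22)

#' Normalize chromosome names
#'
#' Strips any `"chr"` prefix and returns plain chromosome names
#' (`"1".."22"`, `"X"`, ...). The package stores chromosomes without the
#' prefix internally; the prefix is re-added only when writing browser
#' (BED) tracks.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector without `"chr"` prefixes.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

#' Convert interval coordinates between conventions
#'
#' Converts genomic intervals between the package-internal 1-based
#' fully-inclusive convention and BED-style 0-based half-open coordinates.
#' The conversion is exact and invertible: applying it in one direction
#' and then the other is the identity.
#'
#' @param start,end Integer vectors of interval bounds.
#' @param from,to One of `"one_based_inclusive"`, `"zero_based_half_open"`.
#' @return A data.frame with columns `start` and `end` in the target
#'   convention.
#' @export
#' @examples
#' convert_coordinates(100, 200, "one_based_inclusive", "zero_based_half_open")
convert_coordinates <- function(start, end,
                                from = c("one_based_inclusive", "zero_based_half_open"),
                                to = c("zero_based_half_open", "one_based_inclusive")) {
  from <- match.arg(from, c("one_based_inclusive", "zero_based_half_open"))
  to <- match.arg(to, c("one_based_inclusive", "zero_based_half_open"))
  start <- as.numeric(start); end <- as.numeric(end)
  if (from == to) return(data.frame(start = start, end = end))
  if (from == "one_based_inclusive") {
    data.frame(start = start - 1, end = end)
  } else {
    data.frame(start = start + 1, end = end)
  }
}

#' Jaccard overlap of two genomic intervals
#'
#' Intersection length over union length, on 1-based inclusive intervals
#' located on the same chromosome. Vectorized over all arguments. Intervals
#' on different chromosomes have Jaccard 0 by definition; callers are
#' expected to compare intervals chromosome-wise.
#'
#' @param start1,end1,start2,end2 Interval bounds (1-based inclusive).
#' @return Numeric vector of Jaccard indices in `[0, 1]`.
#' @export
interval_jaccard <- function(start1, end1, start2, end2) {
  inter <- pmax(0, pmin(end1, end2) - pmax(start1, start2) + 1)
  uni <- (end1 - start1 + 1) + (end2 - start2 + 1) - inter
  ifelse(uni > 0, inter / uni, 0)
}

# GRanges from an interval data.frame (columns chrom, start, end).
.as_gr <- function(df) {
  GenomicRanges::GRanges(seqnames = as.character(df$chrom),
                         ranges = IRanges::IRanges(start = df$start, end = df$end))
}

# Overlapping row pairs between two interval data.frames (>=1 bp shared,
# same chromosome). With reciprocal > 0, both intervals must additionally
# be covered by the intersection over at least that fraction of their
# lengths. Returns data.frame(i, j) of row indices.
.overlap_pairs <- function(df1, df2, reciprocal = 0) {
  if (nrow(df1) == 0L || nrow(df2) == 0L)
    return(data.frame(i = integer(0), j = integer(0)))
  gr1 <- .as_gr(df1); gr2 <- .as_gr(df2)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr1, gr2))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  if (reciprocal > 0 && length(i)) {
    w <- pmin(df1$end[i], df2$end[j]) - pmax(df1$start[i], df2$start[j]) + 1
    keep <- w >= reciprocal * (df1$end[i] - df1$start[i] + 1) &
      w >= reciprocal * (df2$end[j] - df2$start[j] + 1)
    i <- i[keep]; j <- j[keep]
  }
  data.frame(i = i, j = j)
}

# Single-linkage clusters of intervals under the >=1 bp overlap rule
# (connected components of the interval-overlap graph), by a sorted
# sweep per chromosome: after ordering by start, a new cluster opens
# whenever an interval starts beyond the running maximum end. Book-ended
# intervals (end + 1 == start) are NOT linked. Returns an integer
# cluster id per row of df. Equivalent to clustering with
# GenomicRanges::reduce(min.gapwidth = 0); cross-checked in the tests.
.cluster_intervals <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  ids <- integer(n)
  offset <- 0L
  for (idx in split(seq_len(n), as.character(df$chrom))) {
    o <- idx[order(df$start[idx], df$end[idx])]
    ce <- cummax(df$end[o])
    new_cl <- c(TRUE, df$start[o][-1] > ce[-length(o)])
    ids[o] <- offset + cumsum(new_cl)
    offset <- offset + sum(new_cl)
  }
  ids
}

# Order interval rows by (chromosome, start, end); autosomes numerically.
.interval_order <- function(df) {
  suppressWarnings(cn <- as.numeric(df$chrom))
  cn[is.na(cn)] <- 1e6
  order(cn, as.character(df$chrom), df$start, df$end)
}
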