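# Independent brute-force references. Everything here is all-against-all
# (quadratic) arithmetic plus union-find, deliberately sharing no code
# with the package's interval machinery.

ov1 <- function(c1, s1, e1, c2, s2, e2) c1 == c2 & s1 <= e2 & s2 <= e1

# all-against-all overlapping row pairs between two interval tables
oracle_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a = integer(0), b = integer(0)))
  g <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  hit <- ov1(a$chrom[g$i], a$start[g$i], a$end[g$i],
             b$chrom[g$j], b$start[g$j], b$end[g$j])
  data.frame(a = g$i[hit], b = g$j[hit])
}

# union-find connected components; edges is a 2-column matrix of node ids
oracle_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    r1 <- find(edges[k, 1]); r2 <- find(edges[k, 2])
    if (r1 != r2) parent[r2] <- r1
  }
  vapply(seq_len(n), find, 1L)
}

# quadratic single-linkage clustering of intervals (>=1 bp overlap)
oracle_clusters <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  g <- g[g$i < g$j, , drop = FALSE]
  hit <- ov1(df$chrom[g$i], df$start[g$i], df$end[g$i],
             df$chrom[g$j], df$start[g$j], df$end[g$j])
  oracle_components(n, cbind(g$i[hit], g$j[hit]))
}

# canonical form of a partition for comparison: sorted list of sorted
# member index vectors
canon_partition <- function(ids) {
  grp <- lapply(split(seq_along(ids), ids), sort)
  grp[order(vapply(grp, `[`, 1L, 1L))]
}

# quadratic reference for the whole per-individual congruency merge under
# the partner_rescue policy; returns sorted merged intervals and counters
oracle_merge <- function(calls_a, calls_b) {
  prem <- function(df) {
    if (nrow(df) <= 1L) return(df)
    n <- nrow(df)
    g <- expand.grid(i = seq_len(n), j = seq_len(n))
    g <- g[g$i < g$j, , drop = FALSE]
    hit <- df$direction[g$i] == df$direction[g$j] &
      ov1(df$chrom[g$i], df$start[g$i], df$end[g$i],
          df$chrom[g$j], df$start[g$j], df$end[g$j])
    comp <- oracle_components(n, cbind(g$i[hit], g$j[hit]))
    do.call(rbind, lapply(split(seq_len(n), comp), function(ii)
      data.frame(chrom = df$chrom[ii[1]], start = min(df$start[ii]),
                 end = max(df$end[ii]), direction = df$direction[ii[1]],
                 stringsAsFactors = FALSE)))
  }
  a <- prem(calls_a[c("chrom", "start", "end", "direction")])
  b <- prem(calls_b[c("chrom", "start", "end", "direction")])
  pr <- oracle_pairs(a, b)
  conc <- pr[a$direction[pr$a] == b$direction[pr$b], , drop = FALSE]
  keep_a <- sort(unique(conc$a)); keep_b <- sort(unique(conc$b))
  in_pair_a <- seq_len(nrow(a)) %in% pr$a
  in_pair_b <- seq_len(nrow(b)) %in% pr$b
  counters <- list(
    n_absorbed = length(keep_a) + length(keep_b),
    n_discordant = sum(in_pair_a & !seq_len(nrow(a)) %in% keep_a) +
      sum(in_pair_b & !seq_len(nrow(b)) %in% keep_b),
    n_unsupported = sum(!in_pair_a) + sum(!in_pair_b))
  if (length(keep_a) == 0L)
    return(list(merged = data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), direction = character(0)),
                counters = counters))
  nodes <- rbind(a[keep_a, ], b[keep_b, ])
  e1 <- match(conc$a, keep_a)
  e2 <- length(keep_a) + match(conc$b, keep_b)
  comp <- oracle_components(nrow(nodes), cbind(e1, e2))
  merged <- do.call(rbind, lapply(split(seq_len(nrow(nodes)), comp),
    function(ii) data.frame(chrom = nodes$chrom[ii[1]],
                            start = min(nodes$start[ii]),
                            end = max(nodes$end[ii]),
                            direction = nodes$direction[ii[1]],
                            stringsAsFactors = FALSE)))
  merged <- merged[order(merged$chrom, merged$start, merged$end,
                         merged$direction), , drop = FALSE]
  rownames(merged) <- NULL
  list(merged = merged, counters = counters)
}

# exhaustive pair-count Mann-Whitney U (of the first group)
oracle_u <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))

# random non-overlapping-per-(chrom,direction) call set for one caller,
# mimicking a caller's segmentation output
rand_caller_calls <- function(n, individual = "ind1", caller = "A",
                              chroms = c("1", "2"), max_pos = 50000,
                              max_len = 800) {
  if (n == 0L)
    return(data.frame(individual_id = character(0), caller_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      copy_number = integer(0), n_markers = integer(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  df <- data.frame(individual_id = individual, caller_id = caller,
                   chrom = chrom, start = start, end = start + len - 1L,
                   direction = sample(c("loss", "gain"), n, replace = TRUE),
                   copy_number = NA_integer_, n_markers = NA_integer_,
                   confidence = NA_real_, stringsAsFactors = FALSE)
  # drop within-(chrom,direction) overlaps so the segmentation precondition
  # holds (the pre-merge path is tested separately)
  keep <- rep(TRUE, n)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (keep[i] && keep[j] && df$direction[i] == df$direction[j] &&
        ov1(df$chrom[i], df$start[i], df$end[i],
            df$chrom[j], df$start[j], df$end[j]))
      keep[j] <- FALSE
  }
  df[keep, , drop = FALSE]
}

rand_intervals <- function(n, chroms = c("1", "2"), max_pos = 50000,
                           max_len = 2000) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len - 1L,
             stringsAsFactors = FALSE)
}

sorted_intervals <- function(df) {
  out <- df[order(df$chrom, df$start, df$end), c("chrom", "start", "end"),
            drop = FALSE]
  rownames(out) <- NULL
  out
}

# tiny deterministic map for format tests
toy_map <- function(intervals = NULL, label = "SW") {
  if (is.null(intervals))
    intervals <- data.frame(chrom = c("1", "1", "2"),
                            start = c(101L, 5001L, 901L),
                            end = c(200L, 5600L, 1400L))
  merged <- do.call(rbind, lapply(seq_len(nrow(intervals)), function(i)
    data.frame(individual_id = c("i1", "i2"), chrom = intervals$chrom[i],
               start = intervals$start[i], end = intervals$end[i],
               direction = "loss", n_support_a = 1L, n_support_b = 1L,
               support_a = "A:1", support_b = "B:1",
               population = label, stringsAsFactors = FALSE)))
  build_population_map(merged, label,
                       config = cnvr_config(genome_build = "toy1"),
                       autosome_lengths = c(`1` = 1e6, `2` = 1e6))
}
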