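# CNVR construction: single-linkage clustering across individuals, the
# >=2-individual rule, the cross-population map, and map summaries.

mk_merged <- function(..., population = "SW") {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(individual_id = r[[1]], chrom = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               direction = r[[5]], n_support_a = 1L, n_support_b = 1L,
               support_a = "A:1", support_b = "B:1", population = population,
               stringsAsFactors = FALSE)))
}

toy_cfg <- cnvr_config(genome_build = "toy1")
toy_len <- c(`1` = 1e6, `2` = 1e6)

test_that("two overlapping individuals form a CNVR; singletons do not", {
  m <- mk_merged(list("i1", "1", 100, 200, "loss"),
                 list("i2", "1", 150, 250, "loss"),
                 list("i3", "2", 100, 200, "loss"))
  map <- build_population_map(m, "SW", toy_cfg, toy_len)
  expect_equal(nrow(map$cnvrs), 1L)
  expect_equal(map$cnvrs$start, 100L)
  expect_equal(map$cnvrs$end, 250L)
  expect_equal(map$cnvrs$n_individuals, 2L)
  expect_equal(map$cnvrs$n_loss, 2L)
})

test_that("frequency counts distinct individuals, not events", {
  # one individual fragmented into a loss and an overlapping gain
  m <- mk_merged(list("i1", "1", 100, 200, "loss"),
                 list("i1", "1", 180, 300, "gain"))
  map <- build_population_map(m, "SW", toy_cfg, toy_len)
  expect_equal(nrow(map$cnvrs), 0L)
})

test_that("direction modes cluster jointly or separately", {
  m <- mk_merged(list("i1", "1", 100, 200, "loss"),
                 list("i2", "1", 150, 250, "gain"),
                 list("i3", "1", 160, 240, "loss"))
  agn <- build_population_map(m, "SW", toy_cfg, toy_len)
  expect_equal(nrow(agn$cnvrs), 1L)
  expect_equal(agn$cnvrs$n_loss, 2L)
  expect_equal(agn$cnvrs$n_gain, 1L)
  strat <- build_population_map(
    m, "SW", cnvr_config(direction_mode = "direction_stratified",
                         genome_build = "toy1"), toy_len)
  expect_equal(nrow(strat$cnvrs), 1L) # only the loss pair qualifies
  expect_equal(strat$cnvrs$n_gain, 0L)
})

test_that("cross-population map keeps only regions common to both maps", {
  sw <- build_population_map(
    mk_merged(list("i1", "1", 100, 300, "loss"),
              list("i2", "1", 120, 280, "loss"),
              list("i1", "2", 100, 200, "loss"),
              list("i2", "2", 110, 190, "loss")), "SW", toy_cfg, toy_len)
  rw <- build_population_map(
    mk_merged(list("r1", "1", 250, 400, "gain"),
              list("r2", "1", 260, 380, "gain"),
              list("r1", "2", 300, 400, "loss"),
              list("r2", "2", 310, 390, "loss"), population = "RW"),
    "RW", toy_cfg, toy_len)
  cp <- build_cross_population_map(sw, rw, toy_cfg)
  expect_equal(nrow(cp$cnvrs), 1L)
  expect_equal(cp$cnvrs$chrom, "1")
  expect_equal(cp$cnvrs$start, 100L) # union span
  expect_equal(cp$cnvrs$end, 400L)
  expect_true(cp$cnvrs$n_SW >= 2L && cp$cnvrs$n_RW >= 2L)
  # intersection span option
  cp2 <- build_cross_population_map(
    sw, rw, cnvr_config(cp_span = "intersection", genome_build = "toy1"))
  expect_equal(cp2$cnvrs$start, 250L)
  expect_equal(cp2$cnvrs$end, 300L)
  # symmetry of intervals
  cp_rev <- build_cross_population_map(rw, sw, toy_cfg)
  expect_equal(sorted_intervals(cp_rev$cnvrs), sorted_intervals(cp$cnvrs))
  # every CP CNVR overlaps >= 1 CNVR in each input map
  expect_equal(nrow(oracle_pairs(cp$cnvrs, sw$cnvrs)) > 0, TRUE)
  expect_equal(nrow(oracle_pairs(cp$cnvrs, rw$cnvrs)) > 0, TRUE)
})

test_that("maps with different genome builds refuse to combine", {
  sw <- toy_map()
  rw <- toy_map(label = "RW")
  rw$genome_build <- "hg19"
  expect_error(build_cross_population_map(sw, rw), "build mismatch")
})

test_that("genome fraction is covered length over autosome length", {
  m <- mk_merged(list("i1", "1", 11, 20, "loss"),
                 list("i2", "1", 11, 20, "loss"))
  map <- build_population_map(m, "SW", toy_cfg, c(`1` = 1000))
  expect_equal(genome_fraction(map), 0.01)
  empty <- build_population_map(m[0, ], "SW", toy_cfg, c(`1` = 1000))
  expect_equal(genome_fraction(empty), 0)
  # saturation: CNVRs tiling the whole single chromosome
  tile <- mk_merged(list("i1", "1", 1, 600, "loss"),
                    list("i2", "1", 400, 1000, "loss"))
  full <- build_population_map(tile, "SW", toy_cfg, c(`1` = 1000))
  expect_equal(genome_fraction(full), 1.0)
  # missing chromosome length is an error
  expect_error(genome_fraction(build_population_map(m, "SW", toy_cfg,
                                                    c(`2` = 1000))),
               "no autosome length")
})

test_that("map summaries report counts, median length and member totals", {
  m <- mk_merged(list("i1", "1", 1, 10, "loss"), list("i2", "1", 3, 10, "loss"),
                 list("i1", "1", 1001, 1020, "loss"),
                 list("i2", "1", 1005, 1020, "loss"),
                 list("i1", "2", 1, 30, "gain"), list("i2", "2", 1, 30, "gain"))
  map <- build_population_map(m, "SW", toy_cfg, toy_len)
  s <- map_summary(map)
  expect_equal(s$n_cnvrs, 3L)
  expect_equal(s$median_length, 20)
  expect_equal(s$total_members, 6L)
  expect_equal(sum(s$per_cnvr$n_loss + s$per_cnvr$n_gain), nrow(m))
  e <- map_summary(build_population_map(m[0, ], "SW", toy_cfg, toy_len))
  expect_equal(e$n_cnvrs, 0L)
  expect_equal(e$median_length, 0)
})

test_that("clustering equals the quadratic single-linkage reference", {
  set.seed(77)
  for (k in 1:20) {
    n <- sample(10:60, 1)
    iv <- rand_intervals(n, max_pos = 20000, max_len = 1500)
    m <- data.frame(individual_id = sprintf("i%d", seq_len(n)),
                    chrom = iv$chrom, start = iv$start, end = iv$end,
                    direction = sample(c("loss", "gain"), n, TRUE),
                    population = "SW", stringsAsFactors = FALSE)
    map <- build_population_map(m, "SW", toy_cfg, toy_len)
    want_cl <- oracle_clusters(m)
    keep <- names(which(table(want_cl) >= 2))
    want <- do.call(rbind, lapply(keep, function(cid) {
      ii <- which(want_cl == as.integer(cid))
      data.frame(chrom = m$chrom[ii[1]], start = min(m$start[ii]),
                 end = max(m$end[ii]), stringsAsFactors = FALSE)
    }))
    if (is.null(want))
      want <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0))
    expect_equal(sorted_intervals(map$cnvrs), sorted_intervals(want))
  }
})

test_that("cluster spans equal GenomicRanges::reduce of the members", {
  set.seed(76)
  for (k in 1:10) {
    iv <- rand_intervals(sample(5:50, 1), max_pos = 20000, max_len = 1500)
    # duplicate every interval under a second individual so each cluster
    # passes the >=2-individual rule and all cluster spans surface as CNVRs
    m <- rbind(
      data.frame(individual_id = sprintf("a%d", seq_len(nrow(iv))), iv),
      data.frame(individual_id = sprintf("b%d", seq_len(nrow(iv))), iv))
    m$direction <- "loss"; m$population <- "SW"
    map <- build_population_map(m, "SW", toy_cfg, toy_len)
    red <- GenomicRanges::reduce(
      GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end)),
      min.gapwidth = 0L)
    want <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                       start = BiocGenerics::start(red),
                       end = BiocGenerics::end(red))
    expect_equal(sorted_intervals(map$cnvrs), sorted_intervals(want))
  }
})

test_that("raising min_individuals is monotone and nests CNVRs", {
  set.seed(78)
  iv <- rand_intervals(80, max_pos = 30000, max_len = 2500)
  m <- data.frame(individual_id = sample(sprintf("i%d", 1:15), 80, TRUE),
                  chrom = iv$chrom, start = iv$start, end = iv$end,
                  direction = "loss", population = "SW",
                  stringsAsFactors = FALSE)
  maps <- lapply(2:5, function(t)
    build_population_map(m, "SW", cnvr_config(min_individuals = t,
                                              genome_build = "toy1"), toy_len))
  counts <- vapply(maps, function(x) nrow(x$cnvrs), 1L)
  expect_true(all(diff(counts) <= 0))
  # every CNVR at threshold t+1 is contained in one at threshold t
  for (k in 1:3) {
    hi <- maps[[k + 1]]$cnvrs; lo <- maps[[k]]$cnvrs
    if (nrow(hi) == 0L) next
    pr <- oracle_pairs(hi, lo)
    contained <- vapply(seq_len(nrow(hi)), function(i) {
      j <- pr$b[pr$a == i]
      any(lo$start[j] <= hi$start[i] & lo$end[j] >= hi$end[i])
    }, TRUE)
    expect_true(all(contained))
  }
})

test_that("members lie within their CNVR and cover every base of it", {
  set.seed(79)
  iv <- rand_intervals(60, max_pos = 20000, max_len = 2000)
  m <- data.frame(individual_id = sample(sprintf("i%d", 1:10), 60, TRUE),
                  chrom = iv$chrom, start = iv$start, end = iv$end,
                  direction = sample(c("loss", "gain"), 60, TRUE),
                  population = "SW", stringsAsFactors = FALSE)
  map <- build_population_map(m, "SW", toy_cfg, toy_len)
  for (i in seq_len(nrow(map$cnvrs))) {
    cv <- map$cnvrs[i, ]
    mem <- map$members[map$members$cnvr_id == cv$cnvr_id, ]
    expect_true(all(mem$start >= cv$start & mem$end <= cv$end))
    # single-linkage clusters are contiguous: sweep over sorted members
    mem <- mem[order(mem$start), ]
    expect_equal(min(mem$start), cv$start)
    expect_equal(max(mem$end), cv$end)
    if (nrow(mem) > 1L)
      expect_true(all(mem$start[-1] <= cummax(mem$end)[-nrow(mem)]))
  }
})
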