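# The two-caller congruency check and merge: overlap pairing, direction
# filtering, component merging, conservation, and oracle equivalence.

mk_calls <- function(..., individual = "ind1", caller = "A") {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(individual_id = individual, caller_id = caller,
               chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), direction = r[[4]],
               copy_number = NA_integer_, n_markers = NA_integer_,
               confidence = NA_real_, stringsAsFactors = FALSE)))
}

test_that("overlap pairing uses the >=1 bp rule with inclusive bounds", {
  a <- mk_calls(list("1", 100, 200, "loss"))
  b1 <- mk_calls(list("1", 200, 300, "loss"), caller = "B")
  expect_equal(nrow(find_cross_caller_overlaps(a, b1)), 1L)
  b2 <- mk_calls(list("1", 201, 300, "loss"), caller = "B")
  expect_equal(nrow(find_cross_caller_overlaps(a, b2)), 0L)
  expect_error(find_cross_caller_overlaps(
    a, mk_calls(list("1", 150, 250, "loss"), individual = "other",
                caller = "B")), "mixed individual")
})

test_that("direction-discordant pairs are removed and counted", {
  a <- mk_calls(list("1", 100, 200, "loss"))
  b <- mk_calls(list("1", 150, 250, "gain"), caller = "B")
  res <- merge_individual(a, b)
  expect_equal(nrow(res$merged), 0L)
  expect_equal(res$report$n_discordant_removed, 2L)
  expect_equal(res$report$n_unsupported_removed, 0L)
})

test_that("a call with one concordant and one discordant partner is rescued", {
  a <- mk_calls(list("1", 100, 200, "loss"))
  b <- mk_calls(list("1", 90, 120, "loss"), list("1", 180, 220, "gain"),
                caller = "B")
  res <- merge_individual(a, b)
  expect_equal(nrow(res$merged), 1L)
  expect_equal(res$merged$start, 90L)
  expect_equal(res$merged$end, 200L)
  expect_equal(res$report$n_discordant_removed, 1L) # only b2
  expect_equal(res$report$n_absorbed, 2L)
  # remove_both policy removes the rescued call as well
  res2 <- merge_individual(a, b, cnvr_config(discordance_policy = "remove_both"))
  expect_equal(nrow(res2$merged), 0L)
  expect_equal(res2$report$n_discordant_removed, 2L) # a and b2
  expect_equal(res2$report$n_unsupported_removed, 1L) # b1 lost its partner
})

test_that("calls undetected by the second caller are discarded as unsupported", {
  a <- mk_calls(list("1", 100, 200, "loss"))
  b <- mk_calls(list("2", 100, 200, "loss"), caller = "B")
  res <- merge_individual(a, b)
  expect_equal(nrow(res$merged), 0L)
  expect_equal(res$report$n_unsupported_removed, 2L)
})

test_that("concordant components merge to the union span, including chains", {
  a <- mk_calls(list("1", 100, 200, "loss"))
  b <- mk_calls(list("1", 150, 250, "loss"), caller = "B")
  res <- merge_individual(a, b)
  expect_equal(res$merged[c("start", "end", "direction")],
               data.frame(start = 100L, end = 250L, direction = "loss"))
  # transitive chain a1 - b1 - a2 collapses to one CNV
  a2 <- mk_calls(list("1", 100, 200, "loss"), list("1", 300, 400, "loss"))
  b2 <- mk_calls(list("1", 180, 320, "loss"), caller = "B")
  res2 <- merge_individual(a2, b2)
  expect_equal(nrow(res2$merged), 1L)
  expect_equal(res2$merged$start, 100L)
  expect_equal(res2$merged$end, 400L)
  expect_equal(res2$merged$n_support_a, 2L)
  # intersection span mode intersects the two callers' spans
  res3 <- merge_individual(a2, b2, cnvr_config(merge_span = "intersection"))
  expect_equal(res3$merged$start, 180L)
  expect_equal(res3$merged$end, 320L)
})

test_that("within-caller overlapping calls are pre-merged with a warning", {
  a <- mk_calls(list("1", 100, 200, "loss"), list("1", 150, 260, "loss"))
  b <- mk_calls(list("1", 90, 110, "loss"), caller = "B")
  expect_warning(res <- merge_individual(a, b), "pre-merged")
  expect_equal(res$report$n_premerged_a, 1L)
  expect_equal(res$report$n_input_a, 1L)
  expect_equal(res$merged$end, 260L)
  expect_equal(res$report$n_input_a + res$report$n_input_b,
               res$report$n_absorbed + res$report$n_discordant_removed +
                 res$report$n_unsupported_removed)
})

test_that("merge is symmetric under exchanging caller labels", {
  set.seed(42)
  for (k in 1:10) {
    a <- rand_caller_calls(20, caller = "A")
    b <- rand_caller_calls(20, caller = "B")
    ab <- merge_individual(a, b)$merged
    a2 <- a; a2$caller_id <- "B"
    b2 <- b; b2$caller_id <- "A"
    ba <- merge_individual(b2, a2)$merged
    expect_equal(sorted_intervals(ab), sorted_intervals(ba))
    expect_equal(ab$direction[order(ab$chrom, ab$start)],
                 ba$direction[order(ba$chrom, ba$start)])
  }
})

test_that("merging is idempotent on its own output", {
  set.seed(43)
  for (k in 1:10) {
    a <- rand_caller_calls(25, caller = "A")
    b <- rand_caller_calls(25, caller = "B")
    m1 <- merge_individual(a, b)$merged
    if (nrow(m1) == 0L) next
    again_a <- m1[names(a)[names(a) %in% names(m1)]]
    again_a$caller_id <- "A"; again_a$copy_number <- NA_integer_
    again_a$n_markers <- NA_integer_; again_a$confidence <- NA_real_
    again_b <- again_a; again_b$caller_id <- "B"
    m2 <- merge_individual(again_a, again_b)$merged
    expect_equal(sorted_intervals(m2), sorted_intervals(m1))
  }
})

test_that("merge output and counters equal the quadratic reference", {
  set.seed(44)
  for (k in 1:40) {
    a <- rand_caller_calls(sample(0:40, 1), caller = "A")
    b <- rand_caller_calls(sample(0:40, 1), caller = "B")
    got <- merge_individual(a, b)
    want <- oracle_merge(a, b)
    expect_equal(sorted_intervals(got$merged), sorted_intervals(want$merged))
    expect_equal(got$report$n_absorbed, want$counters$n_absorbed)
    expect_equal(got$report$n_discordant_removed, want$counters$n_discordant)
    expect_equal(got$report$n_unsupported_removed, want$counters$n_unsupported)
  }
})

test_that("every merged CNV has two-caller support within its span", {
  set.seed(45)
  a <- rand_caller_calls(40, caller = "A")
  b <- rand_caller_calls(40, caller = "B")
  m <- merge_individual(a, b)$merged
  expect_true(all(m$n_support_a >= 1L & m$n_support_b >= 1L))
  # same-direction merged CNVs never overlap one another
  for (d in c("loss", "gain")) {
    sub <- m[m$direction == d, , drop = FALSE]
    if (nrow(sub) > 1L)
      expect_true(all(table(oracle_clusters(sub)) == 1L))
  }
})

test_that("population merge reports conserve calls per individual and in total", {
  set.seed(46)
  calls <- do.call(rbind, lapply(sprintf("ind%02d", 1:6), function(ind) {
    rbind(rand_caller_calls(sample(3:25, 1), individual = ind, caller = "A"),
          rand_caller_calls(sample(3:25, 1), individual = ind, caller = "B"))
  }))
  res <- merge_population(calls, "SW")
  per <- res$report$per_individual
  expect_equal(per$n_input_a + per$n_input_b,
               per$n_absorbed + per$n_discordant_removed +
                 per$n_unsupported_removed)
  tot <- res$report$totals
  expect_equal(tot$n_input_a + tot$n_input_b,
               tot$n_absorbed + tot$n_discordant_removed +
                 tot$n_unsupported_removed)
  expect_equal(tot$n_merged, nrow(res$merged))
})

test_that("an individual seen by only one caller loses all calls as unsupported", {
  calls <- rbind(
    mk_calls(list("1", 100, 200, "loss"), list("1", 500, 600, "gain"),
             individual = "lonely", caller = "A"),
    mk_calls(list("1", 120, 220, "loss"), individual = "paired", caller = "A"),
    mk_calls(list("1", 150, 260, "loss"), individual = "paired", caller = "B"))
  expect_warning(res <- merge_population(calls, "SW"), "only one caller")
  per <- res$report$per_individual
  expect_equal(per$n_unsupported_removed[per$individual_id == "lonely"], 2L)
  expect_equal(nrow(res$merged), 1L)
  expect_equal(res$merged$individual_id, "paired")
})
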