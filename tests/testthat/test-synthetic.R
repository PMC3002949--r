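# The synthetic-data generator: determinism, truth labeling, degenerate
# noise-free behaviour, planted-rate recovery, and population realism.

test_that("generation is deterministic given the seed", {
  d1 <- generate_synthetic_data(synthetic_truth(seed = 5))
  d2 <- generate_synthetic_data(synthetic_truth(seed = 5))
  expect_identical(d1$calls, d2$calls)
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$catalog, d2$catalog)
  expect_identical(d1$carriers, d2$carriers)
  d3 <- generate_synthetic_data(synthetic_truth(seed = 6))
  expect_false(identical(d1$calls, d3$calls))
})

test_that("every emitted call carries exactly one truth label", {
  d <- generate_synthetic_data(synthetic_truth(seed = 8))
  expect_true(all(d$calls$origin %in%
                    c("locus", "background", "hypernoise", "false_positive")))
  expect_true(all(!is.na(d$calls$locus_id[d$calls$origin == "locus"])))
  expect_true(all(is.na(d$calls$locus_id[d$calls$origin != "locus"])))
})

test_that("the noise-free scenario makes both callers agree exactly", {
  d <- generate_synthetic_data(synthetic_truth(seed = 9, scenario = "noise_free"))
  key <- function(caller) {
    sub <- d$calls[d$calls$caller_id == caller, ]
    sort(paste(sub$individual_id, sub$chrom, sub$start, sub$end, sub$direction))
  }
  expect_identical(key("A"), key("B"))
  # merge output equals planted carrier events exactly
  sw <- merge_population(d$calls[d$calls$population == "SW", ], "SW",
                         cnvr_config(genome_build = "toy1"))
  loci <- d$truth$loci
  car <- d$carriers[d$carriers$population == "SW", ]
  want <- merge(car, loci, by = "locus_id")
  expect_equal(
    sort(paste(sw$merged$individual_id, sw$merged$chrom, sw$merged$start,
               sw$merged$end, sw$merged$direction)),
    sort(paste(want$individual_id, want$chrom, want$start, want$end,
               want$direction)))
  expect_equal(sw$report$totals$n_discordant_removed, 0)
  expect_equal(sw$report$totals$n_unsupported_removed, 0)
})

test_that("the planted direction-flip rate is recovered from merge reports", {
  truth <- synthetic_truth(seed = 10, scenario = "calibration")
  d <- generate_synthetic_data(truth)
  # label-level check: flipped call pairs among locus-derived events
  locus_calls <- d$calls[d$calls$origin == "locus", ]
  n_events <- length(unique(locus_calls$event_id))
  n_flipped <- length(unique(locus_calls$event_id[locus_calls$flipped]))
  expect_gt(n_events, 2000)
  phat <- n_flipped / n_events
  ci <- 2.576 * sqrt(0.1 * 0.9 / n_events)
  expect_lt(abs(phat - truth$flip_rate), ci)
})

test_that("african-style parameters reproduce the planted ordering of medians", {
  d <- generate_synthetic_data(synthetic_truth(seed = 12,
                                               scenario = "african_shift"))
  for (caller in c("A", "B")) {
    sub <- d$calls[d$calls$caller_id == caller, ]
    sw <- summarize_individuals(sub[sub$population == "SW", ], "SW")
    rw <- summarize_individuals(sub[sub$population == "RW", ], "RW")
    sw <- sw[!sw$excluded, ]; rw <- rw[!rw$excluded, ]
    expect_gt(median(rw$n_cnvs), median(sw$n_cnvs))
    expect_lt(median(rw$mean_length, na.rm = TRUE),
              median(sw$mean_length, na.rm = TRUE))
  }
  # hypervariable individuals exceed the exclusion threshold
  sub <- d$calls[d$calls$caller_id == "A" & d$calls$population == "SW", ]
  s <- summarize_individuals(sub, "SW")
  expect_equal(sum(s$excluded), unname(d$truth$n_hypervariable["SW"]))
})

test_that("infeasible designs are rejected", {
  expect_error(synthetic_truth(seed = 1, n_cnvrs = 500L,
                               autosome_length = 1e5), "infeasible")
  expect_error(synthetic_truth(seed = 1, flip_rate = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_truth(seed = 1, n_shared = 30L), "n_shared")
  expect_error(synthetic_truth(seed = 1, nonsense = 2), "unknown parameter")
})

test_that("recovery scoring behaves at the extremes", {
  res <- run_synthetic_pipeline("noise_free", seed = 14)
  s <- res$score$summary
  expect_equal(s$recall, rep(1, 3))
  expect_equal(s$precision, rep(1, 3))
  expect_equal(s$mean_jaccard, rep(1, 3))
  # an empty map scores zero recall
  empty <- build_population_map(res$result$merged$SW[0, ], "SW",
                                cnvr_config(genome_build = "toy1"),
                                res$data$truth$genome)
  s0 <- score_against_truth(list(SW = empty), res$data)
  expect_equal(s0$summary$recall, 0)
})

test_that("written synthetic files read back into the same calls", {
  d <- generate_synthetic_data(synthetic_truth(seed = 15))
  dir <- tempfile("synth")
  paths <- write_synthetic_data(d, dir)
  back <- read_cnv_calls(paths[["calls_SW_A"]], "generic_tsv", caller_id = "A")
  orig <- d$calls[d$calls$population == "SW" & d$calls$caller_id == "A", ]
  cols <- c("individual_id", "chrom", "start", "end", "direction")
  o1 <- orig[cols]; o1 <- o1[do.call(order, o1), ]; rownames(o1) <- NULL
  b1 <- back[cols]; b1 <- b1[do.call(order, b1), ]; rownames(b1) <- NULL
  expect_equal(b1, o1)
  genes <- read_features(paths[["genes"]], kind = "gene")
  expect_equal(sorted_intervals(genes), sorted_intervals(d$genes))
  cat <- read_features(paths[["catalog"]], kind = "catalog_cnv", format = "dgv")
  expect_equal(sorted_intervals(cat), sorted_intervals(d$catalog))
})
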