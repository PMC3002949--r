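# Ground-truthed synthetic two-caller, two-population CNV call sets.
# The generator plants CNVR loci on a toy genome, samples carriers per
# population frequency, and emulates the caller phenomena the pipeline
# must survive: over-fragmentation, boundary jitter, direction-discordant
# call pairs, and caller-private false positives.

#' Define a synthetic study design (ground truth)
#'
#' Fixes every parameter of a synthetic two-caller, two-population study:
#' toy genome, planted CNVR loci (positions, directions, per-population
#' frequencies, shared status), per-population background-CNV
#' distributions, and the caller noise model. Generation from the same
#' truth is fully deterministic given the seed.
#'
#' Scenarios:
#' \describe{
#'   \item{`default`}{20 planted CNVRs (8 shared, 6 per population
#'     specific), frequencies 0.05-0.4, 100 individuals per population,
#'     boundary jitter sd 2 kb, fragmentation probability 0.3 (caller A) /
#'     0.05 (caller B), 5 false positives per individual per caller,
#'     direction-flip rate 0.02.}
#'   \item{`noise_free`}{As default with fragmentation, jitter, false
#'     positives and flips all zero: both callers emit identical calls and
#'     the merge output equals the planted carrier events exactly.}
#'   \item{`african_shift`}{Adds population-specific background CNVs
#'     reproducing the observed Sub-Saharan pattern of more, shorter CNVs
#'     per individual (negative-binomial counts: mean 30 vs 60; log-normal
#'     lengths: median 100 kb vs 40 kb), plus hypervariable individuals
#'     exceeding the 500-call exclusion threshold.}
#'   \item{`calibration`}{40 shared loci at frequency 0.35 with
#'     direction-flip rate 0.10 and no other noise, yielding >2000
#'     locus-derived call pairs for discordance-rate recovery.}
#' }
#'
#' @param seed Integer seed; all generation derives from it.
#' @param scenario One of `"default"`, `"noise_free"`, `"african_shift"`,
#'   `"calibration"`.
#' @param ... Named overrides of individual parameters (see the fields of
#'   the returned object).
#' @return list of class `synthetic_truth`, including the planted `loci`
#'   table (`locus_id`, `chrom`, `start`, `end`, `direction`, per-population
#'   frequencies, `shared`).
#' @export
synthetic_truth <- function(seed = 1L,
                            scenario = c("default", "noise_free",
                                         "african_shift", "calibration"),
                            ...) {
  scenario <- match.arg(scenario)
  p <- list(
    seed = as.integer(seed), scenario = scenario,
    populations = c("SW", "RW"),
    n_individuals = c(SW = 100L, RW = 100L),
    n_autosomes = 4L, autosome_length = 1e7,
    n_cnvrs = 20L, n_shared = 8L,
    freq_range = c(0.05, 0.4),
    locus_length_meanlog = log(1e5), locus_length_sdlog = 0.5,
    locus_length_clamp = c(2e4, 5e5), locus_min_separation = 1e5,
    fragmentation = c(A = 0.3, B = 0.05),
    jitter_sd = 2000, fp_rate = c(A = 5, B = 5), flip_rate = 0.02,
    fp_length_meanlog = log(8e3), fp_length_sdlog = 0.6,
    background_count_mean = c(SW = 0, RW = 0),
    background_count_dispersion = c(SW = 10, RW = 10),
    background_length_meanlog = c(SW = log(1e5), RW = log(4e4)),
    background_length_sdlog = c(SW = 0.6, RW = 0.6),
    n_hypervariable = c(SW = 0L, RW = 0L), hyper_n_calls = 600L,
    exclusion_threshold = 500L,
    n_neutral_genes = 20L,
    catalog_records_per_locus = 3L, catalog_n_background = 30L,
    n_validation_individuals = 9L, validation_recall = 0.6,
    genome_build = "toy1")
  presets <- switch(scenario,
    default = list(),
    noise_free = list(fragmentation = c(A = 0, B = 0), jitter_sd = 0,
                      fp_rate = c(A = 0, B = 0), flip_rate = 0),
    african_shift = list(background_count_mean = c(SW = 30, RW = 60),
                         n_hypervariable = c(SW = 2L, RW = 2L)),
    calibration = list(n_cnvrs = 40L, n_shared = 40L,
                       freq_range = c(0.35, 0.35), flip_rate = 0.10,
                       fragmentation = c(A = 0, B = 0), jitter_sd = 0,
                       fp_rate = c(A = 0, B = 0)))
  p[names(presets)] <- presets
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots

  if (p$flip_rate < 0 || p$flip_rate > 1 || any(p$fragmentation < 0) ||
      any(p$fragmentation > 1) || any(p$freq_range < 0) || any(p$freq_range > 1))
    stop("rates and frequencies must lie in [0, 1]")
  if (p$n_shared > p$n_cnvrs) stop("n_shared cannot exceed n_cnvrs")

  set.seed(p$seed)
  genome <- stats::setNames(rep(p$autosome_length, p$n_autosomes),
                            as.character(seq_len(p$n_autosomes)))
  p$genome <- genome
  p$loci <- .place_loci(p)
  structure(p, class = "synthetic_truth")
}

# Place non-overlapping loci (>= min separation apart) on the toy genome.
.place_loci <- function(p) {
  n <- p$n_cnvrs
  lens <- pmin(pmax(round(stats::rlnorm(n, p$locus_length_meanlog,
                                        p$locus_length_sdlog)),
                    p$locus_length_clamp[1]), p$locus_length_clamp[2])
  if (sum(lens + p$locus_min_separation) > sum(p$genome))
    stop("infeasible parameters: planted loci exceed the toy genome")
  chroms <- character(n); starts <- numeric(n)
  placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:1000) {
      ch <- sample(names(p$genome), 1L)
      L <- p$genome[[ch]]
      if (L < lens[i] + 2) next
      s <- floor(stats::runif(1, 1, L - lens[i]))
      e <- s + lens[i] - 1
      clash <- placed$chrom == ch &
        placed$start - p$locus_min_separation <= e &
        placed$end + p$locus_min_separation >= s
      if (!any(clash)) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible parameters: could not place planted loci without collision")
    chroms[i] <- ch; starts[i] <- s
    placed <- rbind(placed, data.frame(chrom = ch, start = s, end = e))
  }
  shared <- c(rep(TRUE, p$n_shared), rep(FALSE, n - p$n_shared))
  n_spec <- n - p$n_shared
  spec_pop <- rep(p$populations, length.out = max(n_spec, 1L))[seq_len(n_spec)]
  loci <- data.frame(
    locus_id = sprintf("L%03d", seq_len(n)),
    chrom = chroms, start = as.integer(starts),
    end = as.integer(starts + lens - 1),
    direction = sample(c("loss", "gain"), n, replace = TRUE),
    shared = shared, stringsAsFactors = FALSE)
  # independent frequency per population; population-specific loci carry
  # frequency 0 in the other population
  specific_to <- c(rep(NA_character_, p$n_shared), spec_pop)
  for (pop in p$populations) {
    f <- stats::runif(n, p$freq_range[1], p$freq_range[2])
    f[!shared & specific_to != pop] <- 0
    loci[[paste0("freq_", pop)]] <- f
  }
  loci
}

# jitter interval bounds (vectorized), clamped to the chromosome and
# kept non-inverted
.jitter_vec <- function(s, e, sd, L) {
  if (sd <= 0)
    return(data.frame(start = as.integer(s), end = as.integer(e)))
  n <- length(s)
  s2 <- pmax(1, pmin(round(s + stats::rnorm(n, 0, sd)), e - 1))
  e2 <- pmin(L, pmax(round(e + stats::rnorm(n, 0, sd)), s2 + 1))
  data.frame(start = as.integer(s2), end = as.integer(e2))
}

#' Generate a synthetic two-caller, two-population call set
#'
#' Emits per-individual calls for both callers and populations, plus
#' companion gene models, an external interval catalog, second-platform
#' validation calls, and the carrier record. Every emitted call is
#' labeled with its origin (`locus`, `background`, `hypernoise`,
#' `false_positive`) and, where applicable, the planted locus and whether
#' its direction was flipped. Output is fully deterministic given the
#' truth's seed.
#'
#' @param truth A [synthetic_truth()] object.
#' @return list: `truth`, `calls` (standard call columns plus
#'   `population`, `origin`, `locus_id`, `flipped`, `event_id`), `genes`,
#'   `catalog`, `validation_calls`, `carriers` (`population`, `locus_id`,
#'   `individual_id`).
#' @export
generate_synthetic_data <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth
  set.seed(p$seed + 1L)
  loci <- p$loci
  ind_ids <- lapply(p$populations, function(pop)
    sprintf("%s_%03d", pop, seq_len(p$n_individuals[[pop]])))
  names(ind_ids) <- p$populations

  # --- carriers and true events ------------------------------------------
  carriers <- list(); events <- list()
  eid <- 0L
  for (pop in p$populations) {
    ids <- ind_ids[[pop]]
    for (i in seq_len(nrow(loci))) {
      f <- loci[[paste0("freq_", pop)]][i]
      if (f <= 0) next
      is_carrier <- stats::rbinom(length(ids), 1L, f) == 1L
      if (!any(is_carrier)) next
      cc <- ids[is_carrier]
      carriers[[length(carriers) + 1L]] <-
        data.frame(population = pop, locus_id = loci$locus_id[i],
                   individual_id = cc, stringsAsFactors = FALSE)
      events[[length(events) + 1L]] <- data.frame(
        event_id = sprintf("E%06d", eid + seq_along(cc)),
        population = pop, individual_id = cc,
        chrom = loci$chrom[i], start = loci$start[i], end = loci$end[i],
        direction = loci$direction[i], origin = "locus",
        locus_id = loci$locus_id[i], stringsAsFactors = FALSE)
      eid <- eid + length(cc)
    }
  }
  carriers <- if (length(carriers)) do.call(rbind, carriers) else
    data.frame(population = character(0), locus_id = character(0),
               individual_id = character(0))

  # --- background (private) CNVs and hypervariable individuals ------------
  for (pop in p$populations) {
    ids <- ind_ids[[pop]]
    mu <- p$background_count_mean[[pop]]
    if (mu > 0) {
      counts <- stats::rnbinom(length(ids), mu = mu,
                               size = p$background_count_dispersion[[pop]])
      for (k in seq_along(ids)) {
        if (counts[k] == 0) next
        ev <- .random_events(counts[k], p,
                             meanlog = p$background_length_meanlog[[pop]],
                             sdlog = p$background_length_sdlog[[pop]])
        ev <- cbind(event_id = sprintf("E%06d", eid + seq_len(nrow(ev))),
                    population = pop, individual_id = ids[k], ev,
                    origin = "background", locus_id = NA_character_)
        eid <- eid + nrow(ev)
        events[[length(events) + 1L]] <- ev
      }
    }
    nh <- p$n_hypervariable[[pop]]
    if (nh > 0) {
      for (k in seq_len(nh)) {
        ev <- .random_events(p$hyper_n_calls, p,
                             meanlog = log(5e3), sdlog = 0.4)
        ev <- cbind(event_id = sprintf("E%06d", eid + seq_len(nrow(ev))),
                    population = pop, individual_id = ids[k], ev,
                    origin = "hypernoise", locus_id = NA_character_)
        eid <- eid + nrow(ev)
        events[[length(events) + 1L]] <- ev
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(0), population = character(0),
               individual_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), direction = character(0),
               origin = character(0), locus_id = character(0))
  rownames(events) <- NULL

  # --- direction flips: one caller reports the opposite direction ---------
  flip_caller <- rep(NA_character_, nrow(events))
  if (p$flip_rate > 0 && nrow(events)) {
    flips <- stats::runif(nrow(events)) < p$flip_rate
    flip_caller[flips] <- sample(c("A", "B"), sum(flips), replace = TRUE)
  }

  # --- caller observations: fragmentation + jitter ------------------------
  calls <- list()
  n_ev <- nrow(events)
  for (caller in c("A", "B")) {
    if (n_ev) {
      frag_p <- p$fragmentation[[caller]]
      flipped <- !is.na(flip_caller) & flip_caller == caller
      dir <- ifelse(flipped,
                    ifelse(events$direction == "loss", "gain", "loss"),
                    events$direction)
      len <- events$end - events$start + 1
      do_frag <- frag_p > 0 & len >= 5000 & stats::runif(n_ev) < frag_p
      cut <- events$start + round(len * stats::runif(n_ev, 0.3, 0.7))
      gap <- sample(100:500, n_ev, replace = TRUE)
      # one segment per event; fragmented events add a right-hand segment
      seg_row <- c(seq_len(n_ev), which(do_frag))
      seg_start <- c(events$start, (cut + gap)[do_frag])
      seg_end <- c(ifelse(do_frag, cut - gap, events$end), events$end[do_frag])
      L <- unname(p$genome[events$chrom[seg_row]])
      se <- .jitter_vec(seg_start, seg_end, p$jitter_sd, L)
      calls[[length(calls) + 1L]] <- data.frame(
        population = events$population[seg_row],
        individual_id = events$individual_id[seg_row],
        caller_id = caller, chrom = events$chrom[seg_row],
        start = se$start, end = se$end, direction = dir[seg_row],
        copy_number = ifelse(dir[seg_row] == "loss", 1L, 3L),
        origin = events$origin[seg_row], locus_id = events$locus_id[seg_row],
        flipped = flipped[seg_row], event_id = events$event_id[seg_row],
        stringsAsFactors = FALSE)
    }
    # caller-private false positives
    if (p$fp_rate[[caller]] > 0) {
      ids_all <- unlist(ind_ids, use.names = FALSE)
      pop_of <- rep(p$populations, lengths(ind_ids))
      nfp <- stats::rpois(length(ids_all), p$fp_rate[[caller]])
      if (sum(nfp) > 0) {
        ev <- .random_events(sum(nfp), p, meanlog = p$fp_length_meanlog,
                             sdlog = p$fp_length_sdlog)
        calls[[length(calls) + 1L]] <- data.frame(
          population = rep(pop_of, nfp), individual_id = rep(ids_all, nfp),
          caller_id = caller, chrom = ev$chrom, start = ev$start,
          end = ev$end, direction = ev$direction,
          copy_number = ifelse(ev$direction == "loss", 1L, 3L),
          origin = "false_positive", locus_id = NA_character_,
          flipped = FALSE, event_id = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else NULL
  if (is.null(calls)) {
    calls <- cbind(.empty_calls()[0, ],
                   data.frame(population = character(0), origin = character(0),
                              locus_id = character(0), flipped = logical(0),
                              event_id = character(0)))
  } else {
    calls$n_markers <- NA_integer_
    calls$confidence <- NA_real_
    calls <- calls[order(calls$population, calls$individual_id,
                         calls$caller_id, calls$chrom, calls$start), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }

  genes <- .synthetic_genes(p)
  catalog <- .synthetic_catalog(p)
  validation <- .synthetic_validation(p, events, ind_ids)

  list(truth = p, calls = calls, genes = genes, catalog = catalog,
       validation_calls = validation, carriers = carriers)
}

# n random events anywhere on the toy genome (lengths log-normal)
.random_events <- function(n, p, meanlog, sdlog) {
  chrom <- sample(names(p$genome), n, replace = TRUE)
  len <- pmax(500, round(stats::rlnorm(n, meanlog, sdlog)))
  L <- unname(p$genome[chrom])
  len <- pmin(len, L - 2)
  start <- floor(stats::runif(n, 1, L - len))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len - 1),
             direction = sample(c("loss", "gain"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# one gene inside every planted locus + neutral genes outside all loci
.synthetic_genes <- function(p) {
  loci <- p$loci
  inside <- data.frame(
    name = paste0("GENE_", loci$locus_id), chrom = loci$chrom,
    start = as.integer(loci$start + round(0.25 * (loci$end - loci$start))),
    end = as.integer(loci$start + round(0.75 * (loci$end - loci$start))),
    kind = "gene", stringsAsFactors = FALSE)
  neutral <- list()
  tries <- 0L
  while (length(neutral) < p$n_neutral_genes && tries < 5000L) {
    tries <- tries + 1L
    ch <- sample(names(p$genome), 1L)
    s <- floor(stats::runif(1, 1, p$genome[[ch]] - 1e4))
    e <- s + 1e4 - 1
    clash <- loci$chrom == ch & loci$start <= e & loci$end >= s
    if (any(clash)) next
    neutral[[length(neutral) + 1L]] <- data.frame(
      name = sprintf("GENE_N%03d", length(neutral) + 1L), chrom = ch,
      start = as.integer(s), end = as.integer(e), kind = "gene",
      stringsAsFactors = FALSE)
  }
  out <- rbind(inside, do.call(rbind, neutral))
  rownames(out) <- NULL
  out
}

# external catalog: a few records per planted locus + scattered records,
# plus sex-chromosome records that comparisons must drop
.synthetic_catalog <- function(p) {
  loci <- p$loci
  recs <- list()
  for (i in seq_len(nrow(loci))) {
    len <- loci$end[i] - loci$start[i] + 1
    for (r in seq_len(p$catalog_records_per_locus)) {
      shift <- round(stats::runif(2, -0.2, 0.2) * len)
      s <- max(1, loci$start[i] + shift[1])
      e <- min(p$genome[[loci$chrom[i]]], loci$end[i] + shift[2])
      if (s >= e) { s <- loci$start[i]; e <- loci$end[i] }
      recs[[length(recs) + 1L]] <- data.frame(
        name = sprintf("CAT_%s_%d", loci$locus_id[i], r),
        chrom = loci$chrom[i], start = as.integer(s), end = as.integer(e),
        kind = "catalog_cnv", stringsAsFactors = FALSE)
    }
  }
  bg <- .random_events(p$catalog_n_background, p,
                       meanlog = log(2e4), sdlog = 0.8)
  recs[[length(recs) + 1L]] <- data.frame(
    name = sprintf("CAT_BG_%03d", seq_len(nrow(bg))), chrom = bg$chrom,
    start = bg$start, end = bg$end, kind = "catalog_cnv",
    stringsAsFactors = FALSE)
  recs[[length(recs) + 1L]] <- data.frame(
    name = sprintf("CAT_X_%d", 1:3), chrom = "X",
    start = c(1e5L, 5e5L, 9e5L), end = c(2e5L, 6e5L, 1e6L),
    kind = "catalog_cnv", stringsAsFactors = FALSE)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# second-platform calls: each true event of the validation subsample is
# re-detected with the stated recall probability
.synthetic_validation <- function(p, events, ind_ids) {
  if (p$n_validation_individuals <= 0 || nrow(events) == 0L) {
    return(cbind(.empty_calls()[0, ],
                 data.frame(population = character(0), origin = character(0),
                            event_id = character(0))))
  }
  pop <- p$populations[1]
  vids <- ind_ids[[pop]][seq_len(min(p$n_validation_individuals,
                                     length(ind_ids[[pop]])))]
  ev <- events[events$individual_id %in% vids, , drop = FALSE]
  detected <- stats::runif(nrow(ev)) < p$validation_recall
  ev <- ev[detected, , drop = FALSE]
  if (nrow(ev) == 0L)
    return(cbind(.empty_calls()[0, ],
                 data.frame(population = character(0), origin = character(0),
                            event_id = character(0))))
  se <- .jitter_vec(ev$start, ev$end, p$jitter_sd,
                    unname(p$genome[ev$chrom]))
  out <- data.frame(population = pop, individual_id = ev$individual_id,
                    caller_id = "A", chrom = ev$chrom,
                    start = se$start, end = se$end, direction = ev$direction,
                    copy_number = ifelse(ev$direction == "loss", 1L, 3L),
                    n_markers = NA_integer_, confidence = NA_real_,
                    origin = "validation", event_id = ev$event_id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Score built CNVR maps against the planted truth
#'
#' A planted locus is *expected* in a population map when at least two
#' distinct individuals of that population carry it (the minimum to form
#' a CNVR), and in the cross-population map when it is shared and
#' carrier-supported in both populations. Each expected locus is matched
#' to the map CNVR with the highest Jaccard overlap; it counts as
#' detected at Jaccard >= `jaccard_threshold`. Precision is the fraction
#' of map CNVRs matching an expected locus at the same threshold.
#'
#' @param maps Named list of `cnvr_map` objects; names must be population
#'   labels of the truth and/or `"CP"`.
#' @param data Output of [generate_synthetic_data()].
#' @param jaccard_threshold Detection threshold (default 0.5).
#' @param min_individuals Carrier support required for a locus to be
#'   expected (default 2).
#' @return list with `per_locus` (map, locus_id, best_jaccard, detected)
#'   and `summary` (map, n_expected, n_cnvrs, recall, precision).
#' @export
score_against_truth <- function(maps, data, jaccard_threshold = 0.5,
                                min_individuals = 2L) {
  truth <- data$truth
  carriers <- data$carriers
  support <- function(pop) {
    n <- tapply(carriers$individual_id[carriers$population == pop],
                carriers$locus_id[carriers$population == pop],
                function(x) length(unique(x)))
    names(which(n >= min_individuals))
  }
  expected_for <- function(label) {
    if (label %in% truth$populations) return(support(label))
    if (label == "CP") {
      shared <- truth$loci$locus_id[truth$loci$shared]
      return(Reduce(intersect, c(lapply(truth$populations, support),
                                 list(shared))))
    }
    stop("unknown map label: ", label)
  }
  per <- list(); summ <- list()
  for (label in names(maps)) {
    map <- maps[[label]]
    exp_ids <- expected_for(label)
    loci <- truth$loci[truth$loci$locus_id %in% exp_ids, , drop = FALSE]
    cv <- map$cnvrs
    bestj <- function(ch, s, e, df) {
      same <- df$chrom == ch
      if (!any(same)) return(0)
      max(interval_jaccard(s, e, df$start[same], df$end[same]))
    }
    lj <- vapply(seq_len(nrow(loci)), function(i)
      bestj(loci$chrom[i], loci$start[i], loci$end[i], cv), 1.0)
    per[[label]] <- data.frame(
      map = label, locus_id = loci$locus_id, best_jaccard = lj,
      detected = lj >= jaccard_threshold, stringsAsFactors = FALSE)
    cj <- vapply(seq_len(nrow(cv)), function(i)
      bestj(cv$chrom[i], cv$start[i], cv$end[i], loci), 1.0)
    summ[[label]] <- data.frame(
      map = label, n_expected = nrow(loci), n_cnvrs = nrow(cv),
      recall = if (nrow(loci)) mean(lj >= jaccard_threshold) else NA_real_,
      precision = if (nrow(cv)) mean(cj >= jaccard_threshold) else NA_real_,
      mean_jaccard = if (nrow(loci)) mean(lj) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(per_locus = do.call(rbind, per), summary = do.call(rbind, summ))
}

#' Write a synthetic data set to disk in the pipeline's input dialects
#'
#' Emits one generic caller TSV per population per caller, a BED4 gene
#' file, a DGV-style catalog TSV, a validation-call TSV, and the truth
#' record (loci + carriers + parameter echo) — exactly the formats
#' [read_cnv_calls()] and [read_features()] ingest.
#'
#' @param data Output of [generate_synthetic_data()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_data <- function(data, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (pop in data$truth$populations) {
    for (caller in c("A", "B")) {
      sub <- data$calls[data$calls$population == pop &
                          data$calls$caller_id == caller, , drop = FALSE]
      f <- file.path(out_dir, sprintf("calls_%s_%s.tsv", pop, caller))
      utils::write.table(sub[c("individual_id", "chrom", "start", "end",
                               "copy_number")],
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[sprintf("calls_%s_%s", pop, caller)] <- f
    }
  }
  gf <- file.path(out_dir, "genes.bed")
  bed <- convert_coordinates(data$genes$start, data$genes$end,
                             "one_based_inclusive", "zero_based_half_open")
  writeLines(sprintf("chr%s\t%d\t%d\t%s", data$genes$chrom,
                     as.integer(bed$start), as.integer(bed$end),
                     data$genes$name), gf)
  paths["genes"] <- gf
  cf <- file.path(out_dir, "catalog.tsv")
  writeLines(sprintf("%s\tchr%s\t%d\t%d", data$catalog$name,
                     data$catalog$chrom, data$catalog$start,
                     data$catalog$end), cf)
  paths["catalog"] <- cf
  vf <- file.path(out_dir, "validation_calls.tsv")
  utils::write.table(data$validation_calls[c("individual_id", "chrom",
                                             "start", "end", "copy_number")],
                     vf, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["validation"] <- vf
  tf <- file.path(out_dir, "truth_loci.tsv")
  utils::write.table(data$truth$loci, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth_loci"] <- tf
  cr <- file.path(out_dir, "truth_carriers.tsv")
  utils::write.table(data$carriers, cr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth_carriers"] <- cr
  pe <- file.path(out_dir, "truth_params.txt")
  scalar <- Filter(function(x) is.atomic(x) && length(x) <= 4,
                   unclass(data$truth)[setdiff(names(data$truth),
                                               c("loci", "genome"))])
  writeLines(vapply(names(scalar), function(k)
    sprintf("%s = %s", k, paste(scalar[[k]], collapse = ",")), ""), pe)
  paths["params"] <- pe
  invisible(paths)
}
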