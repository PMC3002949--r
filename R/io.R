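# Readers and writers for every external file the pipeline touches.
# Internal convention everywhere: 1-based, fully-inclusive coordinates,
# chromosome names without a "chr" prefix, autosomes only.

.DIRECTIONS <- c("loss", "gain")

# direction from an integer copy number; cn = 2 is copy-neutral and invalid.
.direction_from_cn <- function(cn) {
  ifelse(cn < 2, "loss", ifelse(cn > 2, "gain", NA_character_))
}

.empty_calls <- function() {
  data.frame(individual_id = character(0), caller_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             direction = character(0), copy_number = integer(0),
             n_markers = integer(0), confidence = numeric(0),
             stringsAsFactors = FALSE)
}

# Validate a calls data.frame against the CnvCall invariants.
.validate_calls <- function(calls, what = "calls") {
  req <- c("individual_id", "chrom", "start", "end", "direction")
  miss <- setdiff(req, names(calls))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")))
  if (nrow(calls)) {
    if (any(calls$start > calls$end)) stop(sprintf("%s: start > end", what))
    if (any(calls$start < 1)) stop(sprintf("%s: start < 1", what))
    if (!all(calls$direction %in% .DIRECTIONS))
      stop(sprintf("%s: direction must be 'loss' or 'gain'", what))
  }
  invisible(calls)
}

#' Read per-individual CNV calls from a caller output file
#'
#' Parses one caller's CNV call file into the internal call table.
#' Chromosome names are normalized (any `"chr"` prefix is stripped),
#' records on non-autosomal chromosomes are dropped and counted, and
#' copy-number-neutral records (`cn = 2`) are rejected: the pipeline only
#' manipulates gains and losses.
#'
#' Supported dialects:
#' \describe{
#'   \item{`penncnv_rawcnv`}{PennCNV `.rawcnv` text: whitespace-separated
#'     fields beginning with `chrN:start-end`, followed by `key=value`
#'     tokens (`numsnp=`, `cn=`, optionally inside `stateS,cn=N`, and
#'     `conf=`) and a sample file name, whose extension (`.txt`,
#'     `.rawcnv`, ...) is stripped to obtain the individual id.}
#'   \item{`birdseye_table`}{Headerless tab-delimited table with columns
#'     individual, chromosome, start, end, copy-number state, confidence,
#'     marker count. The native multi-state copy number is collapsed to
#'     loss/gain at parse time; the magnitude is retained in
#'     `copy_number`.}
#'   \item{`generic_tsv`}{Tab-delimited with a header; required columns
#'     `individual_id`, `chrom`, `start`, `end` and either `copy_number`
#'     or `direction`; optional `n_markers`, `confidence`. This is the
#'     normative ingestion path for callers without a documented text
#'     format.}
#' }
#'
#' @param path Path to the call file.
#' @param dialect One of `"penncnv_rawcnv"`, `"birdseye_table"`,
#'   `"generic_tsv"`.
#' @param caller_id Caller label, `"A"` or `"B"`.
#' @return A data.frame of calls (columns `individual_id`, `caller_id`,
#'   `chrom`, `start`, `end`, `direction`, `copy_number`, `n_markers`,
#'   `confidence`) carrying a `"read_report"` attribute; see
#'   [call_read_report()]. Malformed lines raise an error naming the line
#'   number; out-of-scope records (sex chromosomes, unknown chromosomes,
#'   copy-neutral states) are rejected and categorized, never silently
#'   dropped.
#' @export
read_cnv_calls <- function(path,
                           dialect = c("generic_tsv", "penncnv_rawcnv", "birdseye_table"),
                           caller_id = c("A", "B")) {
  dialect <- match.arg(dialect)
  caller_id <- match.arg(caller_id)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- switch(dialect,
    penncnv_rawcnv = .parse_penncnv(path),
    birdseye_table = .parse_birdseye(path),
    generic_tsv = .parse_generic_tsv(path))
  .finalize_calls(raw, caller_id, n_input = attr(raw, "n_input"))
}

# -- dialect parsers: each returns a data.frame with individual_id, chrom
# (raw), start, end, copy_number or direction, n_markers, confidence, line.

.parse_penncnv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- .empty_penncnv_frame(length(lines))
  for (k in seq_along(lines)) {
    toks <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    m <- regmatches(toks[1],
                    regexec("^(chr)?([0-9XYMTxymt]+):([0-9]+)-([0-9]+)$", toks[1]))[[1]]
    if (length(m) == 0L)
      stop(sprintf("line %d: malformed PennCNV region field '%s'", k, toks[1]))
    kv <- toks[-1]
    cn_tok <- grep("cn=", kv, value = TRUE)
    if (length(cn_tok) == 0L)
      stop(sprintf("line %d: missing cn= field", k))
    cn <- suppressWarnings(as.integer(sub(".*cn=", "", cn_tok[1])))
    if (is.na(cn)) stop(sprintf("line %d: unparseable cn= field", k))
    numsnp_tok <- grep("^numsnp=", kv, value = TRUE)
    conf_tok <- grep("^conf=", kv, value = TRUE)
    sample_tok <- kv[!grepl("=", kv)]
    if (length(sample_tok) == 0L)
      stop(sprintf("line %d: missing sample field", k))
    out$individual_id[k] <- sub("\\.(txt|rawcnv|tsv|csv)$", "", sample_tok[1])
    out$chrom[k] <- m[3]
    out$start[k] <- as.integer(m[4])
    out$end[k] <- as.integer(m[5])
    out$copy_number[k] <- cn
    out$n_markers[k] <- if (length(numsnp_tok))
      suppressWarnings(as.integer(sub("^numsnp=", "", numsnp_tok[1]))) else NA_integer_
    out$confidence[k] <- if (length(conf_tok))
      suppressWarnings(as.numeric(sub("^conf=", "", conf_tok[1]))) else NA_real_
    out$line[k] <- k
  }
  attr(out, "n_input") <- length(lines)
  out
}

.empty_penncnv_frame <- function(n) {
  data.frame(individual_id = character(n), chrom = character(n),
             start = integer(n), end = integer(n), copy_number = integer(n),
             n_markers = integer(n), confidence = numeric(n), line = integer(n),
             stringsAsFactors = FALSE)
}

.parse_birdseye <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) && ncol(df) < 5L)
    stop("birdseye_table requires >= 5 columns: individual, chrom, start, end, copy number")
  out <- data.frame(
    individual_id = as.character(df[[1]]), chrom = as.character(df[[2]]),
    start = suppressWarnings(as.integer(df[[3]])),
    end = suppressWarnings(as.integer(df[[4]])),
    copy_number = suppressWarnings(as.integer(df[[5]])),
    n_markers = if (ncol(df) >= 7) suppressWarnings(as.integer(df[[7]])) else NA_integer_,
    confidence = if (ncol(df) >= 6) suppressWarnings(as.numeric(df[[6]])) else NA_real_,
    line = seq_len(nrow(df)), stringsAsFactors = FALSE)
  bad <- which(is.na(out$start) | is.na(out$end) | is.na(out$copy_number))
  if (length(bad)) stop(sprintf("line %d: malformed birdseye record", bad[1]))
  attr(out, "n_input") <- nrow(df)
  out
}

.parse_generic_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("individual_id", "chrom", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("generic_tsv is missing column(s): ", paste(miss, collapse = ", "))
  if (!any(c("copy_number", "direction") %in% names(df)))
    stop("generic_tsv needs a copy_number or direction column")
  out <- data.frame(
    individual_id = as.character(df$individual_id),
    chrom = as.character(df$chrom),
    start = suppressWarnings(as.integer(df$start)),
    end = suppressWarnings(as.integer(df$end)),
    copy_number = if ("copy_number" %in% names(df))
      suppressWarnings(as.integer(df$copy_number)) else NA_integer_,
    n_markers = if ("n_markers" %in% names(df))
      suppressWarnings(as.integer(df$n_markers)) else NA_integer_,
    confidence = if ("confidence" %in% names(df))
      suppressWarnings(as.numeric(df$confidence)) else NA_real_,
    line = seq_len(nrow(df)) + 1L,  # 1 header line
    stringsAsFactors = FALSE)
  if ("direction" %in% names(df)) out$direction <- as.character(df$direction)
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad)) stop(sprintf("line %d: malformed record", out$line[bad[1]]))
  attr(out, "n_input") <- nrow(df)
  out
}

# Shared rejection logic: sex/unknown chromosomes, copy-neutral calls,
# inverted intervals. Attaches the read report.
.finalize_calls <- function(raw, caller_id, n_input) {
  raw$chrom <- normalize_chrom(raw$chrom)
  if (is.null(raw$direction)) raw$direction <- .direction_from_cn(raw$copy_number)
  # direction given but copy_number too: check consistency
  both <- !is.na(raw$copy_number) & !is.na(raw$direction) & raw$copy_number != 2L
  inconsistent <- both & raw$direction != .direction_from_cn(raw$copy_number)
  if (any(inconsistent))
    stop(sprintf("line %d: direction inconsistent with copy_number",
                 raw$line[which(inconsistent)[1]]))

  is_auto <- raw$chrom %in% autosome_names()
  is_sex <- toupper(raw$chrom) %in% c("X", "Y", "XY", "M", "MT", "23", "24", "25")
  neutral <- !is.na(raw$copy_number) & raw$copy_number == 2L
  no_dir <- is.na(raw$direction) & !neutral
  inverted <- raw$start > raw$end

  category <- rep(NA_character_, nrow(raw))
  category[!is_auto & is_sex] <- "non_autosomal"
  category[!is_auto & !is_sex] <- "unknown_chrom"
  category[is.na(category) & neutral] <- "copy_neutral"
  category[is.na(category) & no_dir] <- "missing_direction"
  category[is.na(category) & inverted] <- "invalid_interval"

  keep <- is.na(category)
  rejected <- data.frame(line = raw$line[!keep], category = category[!keep],
                         stringsAsFactors = FALSE)
  calls <- raw[keep, , drop = FALSE]
  calls <- data.frame(individual_id = calls$individual_id,
                      caller_id = rep(caller_id, nrow(calls)),
                      chrom = calls$chrom, start = calls$start, end = calls$end,
                      direction = calls$direction, copy_number = calls$copy_number,
                      n_markers = calls$n_markers, confidence = calls$confidence,
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  .validate_calls(calls)
  report <- list(
    n_input = n_input,
    n_parsed = nrow(calls),
    n_rejected = nrow(rejected),
    rejected_by_category = if (nrow(rejected))
      table(rejected$category) else table(character(0)),
    rejected = rejected)
  stopifnot(report$n_input == report$n_parsed + report$n_rejected)
  attr(calls, "read_report") <- report
  calls
}

#' Read report of a parsed call file
#'
#' Every input record is accounted for: `n_input = n_parsed + n_rejected`,
#' and each rejection carries its line number and a category
#' (`non_autosomal`, `unknown_chrom`, `copy_neutral`, `missing_direction`,
#' `invalid_interval`).
#'
#' @param calls A call table returned by [read_cnv_calls()].
#' @return A list with counters and the per-line rejection table.
#' @export
call_read_report <- function(calls) {
  rep <- attr(calls, "read_report")
  if (is.null(rep)) stop("no read report attached; was this read by read_cnv_calls()?")
  rep
}

#' Read genomic features (genes, catalogs, validation calls) from disk
#'
#' Reads BED-style or DGV-style interval tables and normalizes them to the
#' internal 1-based inclusive convention. Conversion from 0-based half-open
#' input is exact and invertible. `track`, `browser` and `#` comment lines
#' are skipped.
#'
#' @param path Input file.
#' @param kind Feature kind: `"gene"`, `"catalog_cnv"`, `"catalog_cnvr"`,
#'   `"segdup"` or `"validation_call"`.
#' @param coordinate_convention Convention of the *input file*:
#'   `"zero_based_half_open"` (BED default) or `"one_based_inclusive"`.
#' @param format `"bed"` (chrom, start, end, \[name\]) or `"dgv"`
#'   (id, chrom, start, end; defaults to 1-based inclusive input).
#' @return data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `kind`; rows whose interval is inverted after conversion are rejected
#'   and reported in the `"rejected"` attribute (line numbers).
#' @export
read_features <- function(path,
                          kind = c("gene", "catalog_cnv", "catalog_cnvr",
                                   "segdup", "validation_call"),
                          coordinate_convention = NULL,
                          format = c("bed", "dgv")) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (is.null(coordinate_convention))
    coordinate_convention <- if (format == "bed") "zero_based_half_open" else "one_based_inclusive"
  coordinate_convention <- match.arg(coordinate_convention,
                                     c("zero_based_half_open", "one_based_inclusive"))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser)\\b", lines) & !grepl("^#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), kind = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "rejected") <- data.frame(line = integer(0), reason = character(0))
    return(out)
  }
  fields <- strsplit(lines, "\t| +")
  ncols <- lengths(fields)
  minc <- if (format == "bed") 3L else 4L
  if (any(ncols < minc))
    stop(sprintf("line %d: expected >= %d columns", lineno[which(ncols < minc)[1]], minc))
  get <- function(i) vapply(fields, `[[`, "", i)
  if (format == "bed") {
    chrom <- get(1); s <- as.numeric(get(2)); e <- as.numeric(get(3))
    name <- ifelse(ncols >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
    name[ncols < 4L] <- NA
  } else {
    name <- get(1); chrom <- get(2); s <- as.numeric(get(3)); e <- as.numeric(get(4))
  }
  if (anyNA(s) || anyNA(e))
    stop(sprintf("line %d: non-numeric coordinates",
                 lineno[which(is.na(s) | is.na(e))[1]]))
  conv <- convert_coordinates(s, e, from = coordinate_convention,
                              to = "one_based_inclusive")
  out <- data.frame(name = as.character(name), chrom = normalize_chrom(chrom),
                    start = as.integer(conv$start), end = as.integer(conv$end),
                    kind = kind, stringsAsFactors = FALSE)
  bad <- out$start > out$end
  rejected <- data.frame(line = lineno[bad],
                         reason = rep("start > end after conversion", sum(bad)),
                         stringsAsFactors = FALSE)
  out <- out[!bad, , drop = FALSE]
  noname <- is.na(out$name)
  out$name[noname] <- sprintf("%s_%d", kind, which(noname))
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a CNVR map as a UCSC browser BED track
#'
#' One BED record per CNVR in 0-based half-open coordinates with a `chr`
#' prefix, preceded by a `track` header carrying the map label. The name
#' field encodes the CNVR id, its frequency (distinct individuals) and its
#' gain/loss composition, e.g. `SW_CNVR_00001;n=5;type=loss`. Reading the
#' file back with [read_features()] recovers every interval exactly.
#'
#' @param map A [cnvr_map] object.
#' @param path Output path.
#' @return Invisibly, the output path.
#' @export
write_map_bed <- function(map, path) {
  stopifnot(inherits(map, "cnvr_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="%s" description="CNVR map %s (%s)"',
                     map$label, map$label, map$genome_build), con)
  cv <- map$cnvrs
  if (nrow(cv)) {
    type <- ifelse(cv$n_loss > 0 & cv$n_gain > 0, "mixed",
                   ifelse(cv$n_loss > 0, "loss", "gain"))
    bed <- convert_coordinates(cv$start, cv$end, "one_based_inclusive",
                               "zero_based_half_open")
    writeLines(sprintf("chr%s\t%d\t%d\t%s;n=%d;type=%s",
                       cv$chrom, as.integer(bed$start), as.integer(bed$end),
                       cv$cnvr_id, cv$n_individuals, type), con)
  }
  invisible(path)
}

#' Write a CNVR map as a tab-delimited table
#'
#' Per-CNVR rows with coordinates (1-based inclusive), length, per-population
#' distinct-individual counts and gain/loss member counts.
#'
#' @param map A [cnvr_map] object.
#' @param path Output path.
#' @return Invisibly, the output path.
#' @export
write_cnvr_table <- function(map, path) {
  stopifnot(inherits(map, "cnvr_map"))
  utils::write.table(map$cnvrs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-individual scalar metric table
#'
#' Two-column (`individual_id`, value) or three-column (`individual_id`,
#' `metric`, value) tab-delimited table, e.g. genome-wide SNP
#' heterozygosity per individual. One value per (individual, metric) is
#' enforced.
#'
#' @param path Input file (tab-delimited, header required).
#' @param metric_name Metric name to assign when the file has two columns.
#' @return data.frame with columns `individual_id`, `metric`, `value`.
#' @export
read_metric_table <- function(path, metric_name = "metric") {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) == 2L) {
    out <- data.frame(individual_id = as.character(df[[1]]),
                      metric = metric_name, value = as.numeric(df[[2]]),
                      stringsAsFactors = FALSE)
  } else if (ncol(df) >= 3L) {
    out <- data.frame(individual_id = as.character(df[[1]]),
                      metric = as.character(df[[2]]), value = as.numeric(df[[3]]),
                      stringsAsFactors = FALSE)
  } else stop("metric table needs 2 or 3 columns")
  if (anyDuplicated(out[c("individual_id", "metric")]))
    stop("duplicate (individual, metric) rows in metric table")
  out
}

#' Write merged CNVs as a tab-delimited table
#'
#' @param merged Merged-CNV table from [merge_population()].
#' @param path Output path.
#' @return Invisibly, the output path.
#' @export
write_merged_table <- function(merged, path) {
  cols <- intersect(c("population", "individual_id", "chrom", "start", "end",
                      "direction", "n_support_a", "n_support_b"), names(merged))
  utils::write.table(merged[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
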