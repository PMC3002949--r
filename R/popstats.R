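# Population-difference statistics on per-individual CNV summaries:
# Shapiro-Wilk normality pre-checks (reported as justification metadata)
# and two-sided Mann-Whitney U tests.

#' Summarize CNV calls per individual
#'
#' Per-individual CNV count and mean length, with individuals exceeding
#' the exclusion threshold flagged (not deleted): counts above the
#' threshold indicate caller over-fragmentation or misclassification, and
#' such subjects are excluded from population comparisons.
#'
#' @param calls Call table (raw caller output or merged CNVs) with
#'   `individual_id`, `start`, `end`.
#' @param population_label Population label for all rows.
#' @param exclusion_threshold Flag individuals with more than this many
#'   calls (default 500).
#' @param individuals Optional character vector of all expected
#'   individual ids; ids absent from `calls` get `n_cnvs = 0` and an
#'   undefined (`NA`) mean length.
#' @return data.frame: `individual_id`, `population`, `n_cnvs`,
#'   `mean_length`, `excluded`.
#' @export
summarize_individuals <- function(calls, population_label,
                                  exclusion_threshold = 500L,
                                  individuals = NULL) {
  if (is.null(individuals)) individuals <- unique(calls$individual_id)
  len <- calls$end - calls$start + 1
  n <- vapply(individuals, function(i) sum(calls$individual_id == i), 1L)
  ml <- vapply(individuals, function(i) {
    x <- len[calls$individual_id == i]
    if (length(x)) mean(x) else NA_real_
  }, 1.0)
  out <- data.frame(individual_id = as.character(individuals),
                    population = population_label,
                    n_cnvs = as.integer(n), mean_length = ml,
                    excluded = n > exclusion_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare two populations on a per-individual metric
#'
#' Shapiro-Wilk normality is computed per group and recorded as
#' justification metadata (CNV count and length distributions are
#' typically non-normal); the comparison itself is a two-sided
#' Mann-Whitney U test on the non-excluded individuals. Below 50 per
#' group with no ties the exact distribution is used; otherwise the
#' normal approximation with continuity and tie correction.
#'
#' @param summaries_a,summaries_b Either per-individual summary tables
#'   from [summarize_individuals()] (rows flagged `excluded` are dropped
#'   and reported separately) or plain numeric vectors of per-individual
#'   metric values.
#' @param metric Column to compare when summaries are tables
#'   (`"n_cnvs"` or `"mean_length"`), or a metric name when vectors are
#'   given.
#' @param labels Group labels (defaults to the tables' `population`
#'   values, else `"A"`/`"B"`).
#' @return list of class `cnv_test_result`: `metric`, `labels`, `n`
#'   (per group, after exclusion), `n_excluded`, `shapiro_p`,
#'   `test = "mann_whitney_u"`, `statistic` (U of the first group, the
#'   `W` of [stats::wilcox.test()]), `p_value`, `medians`.
#' @export
compare_populations <- function(summaries_a, summaries_b,
                                metric = c("n_cnvs", "mean_length"),
                                labels = NULL) {
  metric_name <- if (is.numeric(summaries_a)) {
    if (is.character(metric) && length(metric) == 1L) metric else "metric"
  } else match.arg(metric)
  pull <- function(s, which_default) {
    if (is.numeric(s))
      return(list(values = s, label = which_default, n_excluded = 0L))
    keep <- !s$excluded & !is.na(s[[metric_name]])
    list(values = s[[metric_name]][keep],
         label = if ("population" %in% names(s) && nrow(s))
           s$population[1] else which_default,
         n_excluded = sum(s$excluded))
  }
  a <- pull(summaries_a, "A"); b <- pull(summaries_b, "B")
  if (!is.null(labels)) { a$label <- labels[1]; b$label <- labels[2] }
  if (length(a$values) < 3L || length(b$values) < 3L)
    stop("need >= 3 non-excluded individuals per group")
  sw <- function(x) {
    if (length(x) < 3L || length(x) > 5000L || length(unique(x)) == 1L)
      return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a$values, b$values, alternative = "two.sided"))
  out <- list(metric = metric_name,
              labels = c(a$label, b$label),
              n = c(length(a$values), length(b$values)),
              n_excluded = c(a$n_excluded, b$n_excluded),
              shapiro_p = c(sw(a$values), sw(b$values)),
              test = "mann_whitney_u",
              statistic = unname(wt$statistic),
              p_value = wt$p.value,
              medians = c(stats::median(a$values), stats::median(b$values)))
  class(out) <- "cnv_test_result"
  out
}

#' @export
print.cnv_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U, metric '%s': %s (n=%d, median %.4g) vs %s (n=%d, median %.4g)\n",
              x$metric, x$labels[1], x$n[1], x$medians[1],
              x$labels[2], x$n[2], x$medians[2]))
  cat(sprintf("  U = %.4g, p = %.4g (two-sided); Shapiro-Wilk p: %.3g / %.3g; excluded: %d / %d\n",
              x$statistic, x$p_value, x$shapiro_p[1], x$shapiro_p[2],
              x$n_excluded[1], x$n_excluded[2]))
  invisible(x)
}
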