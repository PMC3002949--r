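# Gene screening: which genes overlap a map's CNVRs, and how affected
# genes partition into shared and population-specific sets.

# Gene key: plain name, disambiguated as name@chrom when the same name
# occurs on more than one chromosome.
.gene_keys <- function(genes) {
  key <- as.character(genes$name)
  dup <- names(which(tapply(genes$chrom, genes$name, function(ch)
    length(unique(ch)) > 1L)))
  amb <- key %in% dup
  key[amb] <- paste0(key[amb], "@", genes$chrom[amb])
  key
}

#' Screen a CNVR map for overlapping genes
#'
#' Reports every (gene, CNVR) pair sharing at least one base; full gene
#' spans are used. The distinct-gene count deduplicates genes hit by more
#' than one CNVR.
#'
#' @param map A `cnvr_map`.
#' @param genes Gene features (data.frame with `name`, `chrom`, `start`,
#'   `end`), e.g. from [read_features()] with `kind = "gene"`.
#' @return list with `hits` (data.frame: `map_label`, `gene`, `cnvr_id`,
#'   `overlap_bp`) and `n_genes`, the distinct affected-gene count. The
#'   result is invariant to gene input order.
#' @export
genes_overlapping_map <- function(map, genes) {
  stopifnot(inherits(map, "cnvr_map"))
  genes <- genes[order(.gene_keys(genes)), , drop = FALSE]
  key <- .gene_keys(genes)
  pr <- .overlap_pairs(genes, map$cnvrs)
  hits <- data.frame(
    map_label = rep(map$label, nrow(pr)),
    gene = key[pr$i],
    cnvr_id = map$cnvrs$cnvr_id[pr$j],
    overlap_bp = if (nrow(pr))
      pmin(genes$end[pr$i], map$cnvrs$end[pr$j]) -
        pmax(genes$start[pr$i], map$cnvrs$start[pr$j]) + 1L else integer(0),
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$gene, hits$cnvr_id), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, n_genes = length(unique(hits$gene)))
}

#' Partition affected genes into shared and population-specific sets
#'
#' Set algebra on the distinct gene names affected in each map: genes
#' copy-number variable in both populations, only in the first, and only
#' in the second. Fractions are computed over the union and sum to 1.
#'
#' @param hits_a,hits_b Results of [genes_overlapping_map()] for the two
#'   population maps, computed against the same gene set.
#' @return list with character vectors `shared`, `only_a`, `only_b`,
#'   `fractions` (named numeric summing to 1) and `n_total` (union size).
#' @export
partition_genes <- function(hits_a, hits_b) {
  ga <- unique(hits_a$hits$gene)
  gb <- unique(hits_b$hits$gene)
  shared <- sort(intersect(ga, gb))
  only_a <- sort(setdiff(ga, gb))
  only_b <- sort(setdiff(gb, ga))
  n <- length(shared) + length(only_a) + length(only_b)
  fr <- if (n > 0)
    c(shared = length(shared) / n, only_a = length(only_a) / n,
      only_b = length(only_b) / n)
  else c(shared = NA_real_, only_a = NA_real_, only_b = NA_real_)
  list(shared = shared, only_a = only_a, only_b = only_b,
       fractions = fr, n_total = n)
}
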