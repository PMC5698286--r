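# Repertoire quantification: per-gene/per-J counting, replicate
# normalization, median frequencies, the binomial activity test and the
# mappability filter.

#' Count deduplicated events per gene, J gene and replicate
#'
#' An event contributes to a gene when its alignment start lies in the gene's
#' 750-bp counting window (half-open) and its strand matches the gene strand.
#' Overlapping counting windows are allowed: the event is counted in every
#' overlapping window and the overlap is flagged.
#'
#' @param events deduplicated events data.frame (`replicate`, `j_id`,
#'   `v_start`, `v_strand`).
#' @param genes gene annotation data.frame.
#' @param windows optional [gene_windows()] result (recomputed if missing).
#' @return long data.frame `gene`, `j`, `replicate`, `count` over the complete
#'   grid, with attribute `overlapping_windows`.
#' @export
count_events <- function(events, genes, windows = NULL) {
  if (is.null(windows)) windows <- gene_windows(genes)
  cw <- window_of(windows, "count")
  ov <- FALSE
  if (nrow(cw) > 1) {
    o <- order(cw$start)
    ov <- any(cw$start[o][-1] < cw$end[o][-nrow(cw)])
    if (ov) message("overlapping counting windows: events counted in every ",
                    "overlapping window")
  }
  js <- sort(unique(events$j_id))
  reps <- sort(unique(events$replicate))
  grid <- expand.grid(gene = genes$id, j = js, replicate = reps,
                      stringsAsFactors = FALSE)
  grid$count <- 0L
  for (g in seq_len(nrow(genes))) {
    hit <- events$v_start >= cw$start[g] & events$v_start < cw$end[g] &
      events$v_strand == genes$strand[g]
    if (!any(hit)) next
    tab <- table(events$j_id[hit], events$replicate[hit])
    for (j in rownames(tab)) {
      for (r in colnames(tab)) {
        sel <- grid$gene == genes$id[g] & grid$j == j &
          grid$replicate == type.convert(r, as.is = TRUE)
        grid$count[sel] <- grid$count[sel] + tab[j, r]
      }
    }
  }
  attr(grid, "overlapping_windows") <- ov
  grid
}

#' Normalize replicates to the median-total replicate
#'
#' Each replicate is scaled by `total(reference) / total(replicate)`, where
#' totals are computed within the chosen scope (all J genes or J1 only) and
#' the reference replicate is the one with the median total (for an even
#' number of replicates, the lower of the two middle totals).
#'
#' @param counts long data.frame `gene`, `j`, `replicate`, `count`.
#' @param scope `"all_J"` or `"J1_only"`.
#' @return `counts` with a `normalized` column; scale factors in the
#'   `scale_factors` attribute.
#' @export
normalize_replicates <- function(counts, scope = c("all_J", "J1_only")) {
  scope <- match.arg(scope)
  in_scope <- if (scope == "J1_only") counts$j == "J1" else rep(TRUE, nrow(counts))
  totals <- tapply(counts$count[in_scope], counts$replicate[in_scope], sum)
  if (any(totals == 0)) stop("replicate with zero total in scope")
  sorted <- sort(as.numeric(totals))
  ref_total <- sorted[ceiling(length(sorted) / 2)]  # lower-median for even n
  factors <- ref_total / as.numeric(totals)
  names(factors) <- names(totals)
  counts$normalized <- counts$count *
    factors[as.character(counts$replicate)]
  attr(counts, "scale_factors") <- factors
  counts
}

#' Median normalized frequency per gene and J
#'
#' @param norm output of [normalize_replicates()].
#' @return data.frame `gene`, `j`, `median_frequency`.
#' @export
median_frequency <- function(norm) {
  agg <- stats::aggregate(normalized ~ gene + j, data = norm, FUN = stats::median)
  names(agg)[3] <- "median_frequency"
  agg
}

#' One-sided binomial enrichment test for gene activity
#'
#' For each gene, tests whether its (rounded median normalized) read count is
#' enriched relative to the V region as a whole: the upper-tail probability
#' `P(X >= n)` for `X ~ Binomial(N, p)` with `p = window_length /
#' v_region_length`. P-values are Benjamini-Hochberg adjusted and genes with
#' `padj < alpha` are called active.
#'
#' @param n per-gene rounded median normalized counts (named vector).
#' @param N rounded median of the per-replicate totals over the V region.
#' @param window_length counting-window length (750 bp).
#' @param v_region_length total V region length.
#' @param alpha adjusted-p threshold for the activity call (default 0.01).
#' @return data.frame `gene`, `n`, `p_value`, `padj`, `active`.
#' @export
binomial_activity_test <- function(n, N, window_length = 750,
                                   v_region_length, alpha = 0.01) {
  stopifnot(v_region_length > window_length, window_length > 0)
  if (any(n > N)) stop("per-gene count exceeds the region total")
  p <- window_length / v_region_length
  p_value <- stats::pbinom(n - 1, size = N, prob = p, lower.tail = FALSE)
  padj <- stats::p.adjust(p_value, method = "BH")
  data.frame(gene = if (is.null(names(n))) seq_along(n) else names(n),
             n = n, p_value = p_value, padj = padj,
             active = padj < alpha, row.names = NULL)
}

#' Call active genes from normalized counts
#'
#' Convenience wrapper: computes the rounded (half-to-even) median of the
#' normalized per-gene counts and the rounded median of the per-replicate
#' totals within the same J scope, then applies [binomial_activity_test()].
#'
#' @param norm output of [normalize_replicates()].
#' @param v_region_length total V region length.
#' @param scope J scope (totals and gene counts are taken within it).
#' @param window_length counting-window length.
#' @param alpha adjusted-p activity threshold.
#' @return activity-call data.frame (see [binomial_activity_test()]).
#' @export
call_active_genes <- function(norm, v_region_length,
                              scope = c("J1_only", "all_J"),
                              window_length = 750, alpha = 0.01) {
  scope <- match.arg(scope)
  sub <- if (scope == "J1_only") norm[norm$j == "J1", ] else norm
  per_gene <- tapply(sub$normalized, list(sub$gene, sub$replicate), sum,
                     default = 0)
  n <- round(apply(per_gene, 1, stats::median))
  N <- round(stats::median(colSums(per_gene)))
  binomial_activity_test(n, N, window_length = window_length,
                         v_region_length = v_region_length, alpha = alpha)
}

#' Exclude genes with low mappability
#'
#' Computes the 85-mer mappability of each gene's 350-bp window and removes
#' genes strictly below the threshold (used for frequency-level analyses, not
#' for activity calling).
#'
#' @param genes gene annotation data.frame.
#' @param reference locus sequence.
#' @param threshold percentage threshold (default 70; genes at exactly the
#'   threshold are retained).
#' @param windows optional precomputed [gene_windows()].
#' @param k k-mer length.
#' @return `genes` restricted to retained rows, with a `mappability` column.
#' @export
apply_mappability_filter <- function(genes, reference, threshold = 70,
                                     windows = NULL, k = 85L) {
  if (is.null(windows)) windows <- gene_windows(genes, nchar(reference))
  mw <- window_of(windows, "mapp")
  mp <- vapply(seq_len(nrow(mw)), function(i)
    mappability(reference, mw$start[i], mw$end[i], k = k), numeric(1))
  genes$mappability <- mp
  genes[is.na(mp) | mp >= threshold, ]
}
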