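# Chromatin feature quantification: peak co-localization, relative
# enrichment and the genes x 79-feature explanatory matrix.

#' Distances from gene centres to the nearest peak summits
#'
#' For one peak set, computes the orientation-relative distance from each
#' gene centre to the closest upstream and downstream peak summit, and labels
#' summits as promoter-associated (upstream of the centre and within 1 kb of
#' the gene start site) or RSS-associated (downstream of the centre and
#' within 1 kb of the gene 3' end). A summit exactly at the centre counts as
#' downstream.
#'
#' @param genes gene annotation data.frame.
#' @param peaks peak data.frame with absolute `summit` positions, or a
#'   narrowPeak-style data.frame with `start` and `peak` offset columns.
#' @return data.frame per gene: `upstream_distance`, `downstream_distance`
#'   (bp, `NA` when no summit on that side), `promoter_associated`,
#'   `rss_associated`.
#' @export
nearest_peak_distances <- function(genes, peaks) {
  summit <- if ("summit" %in% names(peaks)) peaks$summit
            else peaks$start + peaks$peak
  centre <- (genes$start + genes$end) %/% 2L
  fwd <- genes$strand == "+"
  start_site <- ifelse(fwd, genes$start, genes$end)
  end3 <- ifelse(fwd, genes$end, genes$start)
  out <- data.frame(id = genes$id, upstream_distance = NA_real_,
                    downstream_distance = NA_real_,
                    promoter_associated = FALSE, rss_associated = FALSE)
  for (g in seq_len(nrow(genes))) {
    rel <- if (fwd[g]) summit - centre[g] else centre[g] - summit
    up <- rel < 0            # upstream of the centre (orientation-relative)
    down <- rel >= 0         # centre-coincident summits count as downstream
    if (any(up)) out$upstream_distance[g] <- min(-rel[up])
    if (any(down)) out$downstream_distance[g] <- min(rel[down])
    out$promoter_associated[g] <- any(up & abs(summit - start_site[g]) <= 1000)
    out$rss_associated[g] <- any(down & abs(summit - end3[g]) <= 1000)
  }
  out
}

# Reads in a window from a binned track, with fractional overlap for bins
# straddling the window edge.
window_track_count <- function(track, start, end) {
  if (end <= start) return(0)
  olap <- pmin(track$end, end) - pmax(track$start, start)
  keep <- olap > 0
  sum(track$count[keep] * olap[keep] / (track$end[keep] - track$start[keep]))
}

#' Relative enrichment of a window over the locus average
#'
#' Fold enrichment of a window's read count relative to the mean count over a
#' non-overlapping tiling of the locus by windows of identical length,
#' anchored at the locus start.
#'
#' @param track binned track data.frame (`start`, `end`, `count`).
#' @param start,end window (0-based half-open).
#' @param locus_length locus length (defaults to the track extent).
#' @return fold enrichment, `NA` if the locus-wide mean is zero.
#' @export
relative_enrichment <- function(track, start, end,
                                locus_length = max(track$end)) {
  len <- end - start
  stopifnot(len > 0)
  n_tiles <- locus_length %/% len
  tile_counts <- vapply(seq_len(n_tiles) - 1L, function(i)
    window_track_count(track, i * len, (i + 1L) * len), numeric(1))
  m <- mean(tile_counts)
  if (m == 0) return(NA_real_)
  window_track_count(track, start, end) / m
}

#' Assemble the explanatory feature matrix
#'
#' One row per gene; per chromatin dataset, the read counts in the four
#' orientation-relative windows (promoter, RSS, upstream, downstream), plus
#' three genetic features: RIC score, strand (forward 0 / reverse 1) and
#' distance to J1. All columns except strand are min-max scaled to `[0, 1]`
#' over genes; a constant column becomes all zeros with a warning. With the
#' 19 study datasets this yields 4 x 19 + 3 = 79 columns.
#'
#' @param genes gene annotation data.frame (needs `ric_score`, `strand`,
#'   `distance_to_j1`).
#' @param tracks named list of binned track data.frames.
#' @param windows optional precomputed [gene_windows()].
#' @param scale min-max scale the columns (default TRUE).
#' @return numeric matrix, genes x features, rownames = gene ids.
#' @export
build_feature_matrix <- function(genes, tracks, windows = NULL, scale = TRUE) {
  if (is.null(windows)) windows <- gene_windows(genes)
  wtypes <- c("promoter", "rss", "upstream", "downstream")
  cols <- list()
  for (tr in names(tracks)) {
    for (wt in wtypes) {
      iv <- window_of(windows, wt)
      cols[[paste0(tr, "_", wt)]] <- vapply(seq_len(nrow(iv)), function(g)
        window_track_count(tracks[[tr]], iv$start[g], iv$end[g]), numeric(1))
    }
  }
  cols[["ric_score"]] <- genes$ric_score
  cols[["strand"]] <- as.numeric(genes$strand == "-")
  cols[["distance_to_j1"]] <- genes$distance_to_j1
  fm <- do.call(cbind, cols)
  rownames(fm) <- genes$id
  if (scale) {
    for (j in setdiff(colnames(fm), "strand")) {
      rng <- range(fm[, j])
      if (diff(rng) == 0) {
        warning("constant feature column: ", j)
        fm[, j] <- 0
      } else {
        fm[, j] <- (fm[, j] - rng[1]) / diff(rng)
      }
    }
  }
  fm
}
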