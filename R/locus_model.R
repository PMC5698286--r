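# Locus representation: gene annotations, orientation-relative windows and
# k-mer mappability. All internal coordinates are 0-based half-open.

#' Derive the analysis windows for each V gene
#'
#' Computes the six half-open intervals used throughout the analysis, all
#' orientation-relative ("upstream" means 5' of the gene on its own strand):
#'
#' * `promoter`: 500 bp upstream of the gene start to the gene centre
#' * `rss`: gene centre to 500 bp downstream of the 3' end
#' * `upstream` / `downstream`: 500 bp to 3 kb up-/downstream of the gene
#' * `count`: 750 bp extending upstream from the 3' end (read counting)
#' * `mapp`: 350 bp extending upstream from the 3' end (mappability)
#'
#' The gene centre is `floor((start + end) / 2)`, so the promoter and RSS
#' windows tile the gene body exactly (promoter end == RSS start).
#'
#' @param genes data.frame with columns `id`, `start`, `end` (0-based
#'   half-open) and `strand` (`"+"` or `"-"`).
#' @param locus_length optional locus length; windows extending past
#'   `[0, locus_length)` are clipped and flagged in the `clipped` column.
#' @return data.frame, one row per gene, with `<window>_start`/`<window>_end`
#'   columns for each window plus `centre` and `clipped`.
#' @export
gene_windows <- function(genes, locus_length = NULL) {
  stopifnot(all(genes$start < genes$end), all(genes$strand %in% c("+", "-")))
  s <- genes$start
  e <- genes$end
  centre <- (s + e) %/% 2L
  fwd <- genes$strand == "+"

  w <- data.frame(id = genes$id, centre = centre)
  # orientation-relative arithmetic: mirror every window for reverse genes
  w$promoter_start   <- ifelse(fwd, s - 500L, centre)
  w$promoter_end     <- ifelse(fwd, centre,   e + 500L)
  w$rss_start        <- ifelse(fwd, centre,   s - 500L)
  w$rss_end          <- ifelse(fwd, e + 500L, centre)
  w$upstream_start   <- ifelse(fwd, s - 3000L, e + 500L)
  w$upstream_end     <- ifelse(fwd, s - 500L,  e + 3000L)
  w$downstream_start <- ifelse(fwd, e + 500L,  s - 3000L)
  w$downstream_end   <- ifelse(fwd, e + 3000L, s - 500L)
  w$count_start      <- ifelse(fwd, e - 750L, s)
  w$count_end        <- ifelse(fwd, e,        s + 750L)
  w$mapp_start       <- ifelse(fwd, e - 350L, s)
  w$mapp_end         <- ifelse(fwd, e,        s + 350L)

  starts <- grep("_start$", names(w))
  ends <- grep("_end$", names(w))
  clipped <- rep(FALSE, nrow(w))
  for (j in seq_along(starts)) {
    a <- w[[starts[j]]]
    b <- w[[ends[j]]]
    a2 <- pmax(a, 0L)
    b2 <- pmax(b, 0L)
    if (!is.null(locus_length)) {
      a2 <- pmin(a2, as.integer(locus_length))
      b2 <- pmin(b2, as.integer(locus_length))
    }
    clipped <- clipped | a2 != a | b2 != b
    w[[starts[j]]] <- a2
    w[[ends[j]]] <- b2
  }
  w$clipped <- clipped
  w
}

#' Extract one window type as an interval data.frame
#'
#' @param windows output of [gene_windows()].
#' @param type one of `"promoter"`, `"rss"`, `"upstream"`, `"downstream"`,
#'   `"count"`, `"mapp"`.
#' @return data.frame with `id`, `start`, `end`.
#' @export
window_of <- function(windows, type) {
  type <- match.arg(type,
                    c("promoter", "rss", "upstream", "downstream", "count", "mapp"))
  data.frame(id = windows$id,
             start = windows[[paste0(type, "_start")]],
             end = windows[[paste0(type, "_end")]])
}

#' Unique-mappability of a window
#'
#' Percentage of k-mers starting inside the window that occur exactly once in
#' the reference, counting occurrences on both strands (a k-mer whose reverse
#' complement occurs elsewhere is not uniquely mappable, matching aligner
#' semantics). K-mer start positions are taken over `[start, end)`, clipped so
#' that the k-mer fits inside the reference.
#'
#' @param reference locus sequence (single character string).
#' @param start,end window, 0-based half-open.
#' @param k k-mer length (default 85, the aligned read length).
#' @return percentage in `[0, 100]`, or `NA` if the window is shorter than `k`.
#' @export
mappability <- function(reference, start, end, k = 85L) {
  L <- nchar(reference)
  if (end - start < k) return(NA_real_)
  first <- max(start, 0L)
  last <- min(end - 1L, L - k)   # last valid k-mer start
  if (last < first) return(NA_real_)
  starts1 <- (first:last) + 1L   # 1-based
  kmers <- substring(reference, starts1, starts1 + k - 1L)
  occ <- kmer_occurrences(kmers, reference)
  100 * mean(occ == 1L)
}

# Count occurrences of each k-mer (all same width) on both strands of the
# reference, via a constant-width dictionary scan.
kmer_occurrences <- function(kmers, reference) {
  ref <- Biostrings::DNAString(reference)
  subjects <- Biostrings::DNAStringSet(list(ref, Biostrings::reverseComplement(ref)))
  uk <- unique(kmers)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uk))
  counts <- rowSums(Biostrings::vcountPDict(pd, subjects))
  counts[match(kmers, uk)]
}

#' Read a gene annotation (BED6 + RIC side table)
#'
#' @param bed_file BED6 file (0-based half-open) of V genes.
#' @param ric_file TSV with columns `id`, `family`, `pseudogene`, `ric_score`.
#' @param j1_position optional position of the first J gene, used to fill
#'   `distance_to_j1`.
#' @return annotation data.frame.
#' @export
read_gene_annotation <- function(bed_file, ric_file, j1_position = NULL) {
  bed <- utils::read.table(bed_file, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "id",
                                         "score", "strand"))
  side <- utils::read.table(ric_file, sep = "\t", header = TRUE)
  genes <- merge(bed[, c("id", "start", "end", "strand")], side, by = "id",
                 sort = FALSE)
  genes <- genes[order(genes$start), ]
  if (!is.null(j1_position)) {
    end3 <- ifelse(genes$strand == "+", genes$end, genes$start)
    genes$distance_to_j1 <- abs(j1_position - end3)
  }
  stopifnot(all(genes$start < genes$end), all(is.finite(genes$ric_score)))
  rownames(genes) <- NULL
  genes
}

#' Write gene windows as BED (0-based half-open)
#'
#' @param windows output of [gene_windows()].
#' @param file output path.
#' @param types window types to emit.
#' @export
write_windows_bed <- function(windows, file,
                              types = c("promoter", "rss", "upstream",
                                        "downstream", "count", "mapp")) {
  rows <- do.call(rbind, lapply(types, function(t) {
    iv <- window_of(windows, t)
    data.frame(chrom = "locus", start = iv$start, end = iv$end,
               name = paste0(iv$id, "_", t), score = 0L, strand = ".")
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
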