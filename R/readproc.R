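# Read processing: chimaera correction, bait assignment, filtering, unique
# exact alignment of the V read, and UMI-based deduplication.

#' Correct chimaeric J baits from the downstream genomic flank
#'
#' A read 2 that starts with the bait of one J but whose next `width` bases
#' exactly match the genomic flank of a different J was produced by
#' mis-priming; its bait prefix is replaced with the correct J's bait.
#' A downstream segment matching more than one flank is left unchanged and
#' counted as ambiguous.
#'
#' @param read2 character vector of read-2 sequences.
#' @param jgenes data.frame with `id`, `bait`, `flank` columns.
#' @param width number of flank bases compared (exact match).
#' @return list with `read2` (corrected sequences) and `n_corrected`,
#'   `n_ambiguous` counters.
#' @export
correct_chimaeras <- function(read2, jgenes, width = 10L) {
  bait_len <- nchar(jgenes$bait)
  stopifnot(length(unique(bait_len)) == 1)
  bl <- bait_len[1]
  flanks <- substring(jgenes$flank, 1L, width)
  stopifnot(!anyDuplicated(flanks))
  prefix <- substring(read2, 1L, bl)
  bait_j <- match(prefix, jgenes$bait)
  down <- substring(read2, bl + 1L, bl + width)
  flank_j <- match(down, flanks)
  n_amb <- 0L  # distinct exact flanks: ambiguity cannot arise, kept for contract
  fix <- !is.na(bait_j) & !is.na(flank_j) & bait_j != flank_j
  if (any(fix)) {
    read2[fix] <- paste0(jgenes$bait[flank_j[fix]],
                         substring(read2[fix], bl + 1L))
  }
  list(read2 = read2, n_corrected = sum(fix), n_ambiguous = n_amb)
}

#' Assign each read 2 to a J gene by exact bait prefix match
#'
#' @param read2 character vector of read-2 sequences.
#' @param jgenes data.frame with `id` and `bait`.
#' @return character vector of J ids, `NA` for reads without a bait (discard).
#' @export
assign_bait <- function(read2, jgenes) {
  bl <- nchar(jgenes$bait[1])
  jgenes$id[match(substring(read2, 1L, bl), jgenes$bait)]
}

#' Filter read pairs on junction length and anchor presence
#'
#' Fails a pair if fewer than `min_junction` bases follow the bait in read 2,
#' or if bases 7-15 of read 1 (the nine bases after the 6-nt molecular
#' identifier) match neither anchor exactly.
#'
#' @param read1,read2 character vectors.
#' @param anchors the two anchor sequences (9 nt each).
#' @param bait_length bait length in read 2.
#' @param min_junction minimum junction length (default 20).
#' @return character vector: `"pass"`, `"short_junction"` or `"no_anchor"`.
#' @export
filter_pair <- function(read1, read2, anchors, bait_length = 20L,
                        min_junction = 20L) {
  res <- rep("pass", length(read1))
  res[nchar(read2) - bait_length < min_junction] <- "short_junction"
  anchor_seen <- substring(read1, 7L, 15L)
  res[res == "pass" & !(anchor_seen %in% anchors)] <- "no_anchor"
  res
}

#' Align clipped V reads uniquely to the reference
#'
#' Matches `read1[15:]` (0-based clip of UMI + anchor) against both strands of
#' the reference. With `max_mismatch = 0` this uses a constant-width
#' dictionary scan; reads with exactly one best-stratum hit get their leftmost
#' reference coordinate (0-based) and strand, all others are discarded.
#'
#' @param read1 character vector of read-1 sequences.
#' @param reference locus sequence (character string).
#' @param clip number of leading bases to drop (UMI + anchor; default 15).
#' @param max_mismatch allowed mismatches in the best stratum (default 0).
#' @return data.frame with `v_start` (0-based leftmost coordinate, `NA` for
#'   discards) and `v_strand`.
#' @export
align_v <- function(read1, reference, clip = 15L, max_mismatch = 0L) {
  vpart <- substring(read1, clip + 1L)
  wd <- unique(nchar(vpart))
  stopifnot(length(wd) == 1)
  L <- nchar(reference)
  uq <- unique(vpart)
  if (max_mismatch == 0L) {
    ref <- Biostrings::DNAString(reference)
    rc <- Biostrings::reverseComplement(ref)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(uq))
    mf <- Biostrings::matchPDict(pd, ref)
    mr <- Biostrings::matchPDict(pd, rc)
    sf <- Biostrings::startIndex(mf)
    sr <- Biostrings::startIndex(mr)
    nf <- lengths(sf)
    nr <- lengths(sr)
    ok <- nf + nr == 1L
    start0 <- rep(NA_integer_, length(uq))
    strand <- rep(NA_character_, length(uq))
    fhit <- ok & nf == 1L
    rhit <- ok & nr == 1L
    start0[fhit] <- vapply(sf[fhit], `[`, integer(1), 1L) - 1L
    # rc coordinate s (1-based) -> forward leftmost 0-based L - s - wd + 1
    start0[rhit] <- L - vapply(sr[rhit], `[`, integer(1), 1L) - wd + 1L
    strand[fhit] <- "+"
    strand[rhit] <- "-"
  } else {
    ref <- Biostrings::DNAString(reference)
    rc <- Biostrings::reverseComplement(ref)
    start0 <- rep(NA_integer_, length(uq))
    strand <- rep(NA_character_, length(uq))
    for (i in seq_along(uq)) {
      hits <- data.frame(pos = integer(0), strand = character(0),
                         mm = integer(0))
      for (str in c("+", "-")) {
        subj <- if (str == "+") ref else rc
        m <- Biostrings::matchPattern(uq[i], subj, max.mismatch = max_mismatch)
        if (length(m) > 0) {
          mm <- vapply(seq_along(m), function(h)
            sum(strsplit(as.character(m[[h]]), "")[[1]] !=
                  strsplit(uq[i], "")[[1]]), integer(1))
          pos <- Biostrings::start(m)
          if (str == "-") pos <- L - pos - wd + 2L
          hits <- rbind(hits, data.frame(pos = pos - 1L, strand = str, mm = mm))
        }
      }
      if (nrow(hits) > 0) {
        best <- hits[hits$mm == min(hits$mm), ]
        if (nrow(best) == 1L) {
          start0[i] <- best$pos
          strand[i] <- best$strand
        }
      }
    }
  }
  idx <- match(vpart, uq)
  data.frame(v_start = start0[idx], v_strand = strand[idx])
}

#' Deduplicate recombination events by (UMI, junction, alignment start)
#'
#' Retains one representative per distinct key within each replicate (the
#' first in input order after a stable sort by key), mirroring PCR-duplicate
#' removal.
#'
#' @param events data.frame with columns `replicate`, `umi`, `junction`,
#'   `v_start` (other columns carried through).
#' @return deduplicated data.frame.
#' @export
deduplicate <- function(events) {
  key <- paste(events$replicate, events$umi, events$junction, events$v_start,
               sep = "\r")
  ord <- order(key, seq_len(nrow(events)))
  ev <- events[ord, ]
  ev <- ev[!duplicated(key[ord]), ]
  rownames(ev) <- NULL
  ev
}

#' Run the full read-processing pipeline
#'
#' Chimaera correction, bait assignment (discarding bait-less reads), junction
#' and anchor filters, unique alignment of the clipped V read, and
#' deduplication, with per-stage accounting.
#'
#' @param read1,read2 named character vectors of mate sequences.
#' @param replicate replicate id per pair (scalar or vector).
#' @param jgenes data.frame with `id`, `bait`, `flank`.
#' @param reference locus sequence.
#' @param anchors the two anchor sequences.
#' @param max_mismatch alignment mismatch allowance (default 0, exact).
#' @param chimaera_width flank width for chimaera correction.
#' @return list with `events` (deduplicated data.frame: `replicate`, `j_id`,
#'   `umi`, `junction`, `v_start`, `v_strand`, `read_id`) and `stage_counts`.
#' @export
process_reads <- function(read1, read2, replicate = 1L, jgenes, reference,
                          anchors, max_mismatch = 0L, chimaera_width = 10L) {
  stopifnot(length(read1) == length(read2))
  n0 <- length(read1)
  replicate <- rep_len(replicate, n0)
  cc <- correct_chimaeras(read2, jgenes, width = chimaera_width)
  read2 <- cc$read2
  j_id <- assign_bait(read2, jgenes)
  keep <- !is.na(j_id)
  n_bait <- sum(keep)
  read1 <- read1[keep]
  read2 <- read2[keep]
  j_id <- j_id[keep]
  replicate <- replicate[keep]

  bl <- nchar(jgenes$bait[1])
  filt <- filter_pair(read1, read2, anchors, bait_length = bl)
  pass <- filt == "pass"
  n_filter <- sum(pass)
  read1 <- read1[pass]
  read2 <- read2[pass]
  j_id <- j_id[pass]
  replicate <- replicate[pass]

  umi <- substring(read1, 1L, 6L)
  junction <- substring(read2, bl + 1L)
  aln <- align_v(read1, reference, max_mismatch = max_mismatch)
  aligned <- !is.na(aln$v_start)
  events <- data.frame(replicate = replicate[aligned],
                       j_id = j_id[aligned],
                       umi = umi[aligned],
                       junction = junction[aligned],
                       v_start = aln$v_start[aligned],
                       v_strand = aln$v_strand[aligned],
                       read_id = names(read1)[aligned] %||% NA_character_)
  n_aligned <- nrow(events)
  events <- deduplicate(events)
  stage_counts <- data.frame(
    stage = c("input", "bait_assigned", "filtered", "aligned_unique",
              "deduplicated"),
    reads = c(n0, n_bait, n_filter, n_aligned, nrow(events)),
    corrected_chimaeras = c(cc$n_corrected, NA, NA, NA, NA))
  list(events = events, stage_counts = stage_counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
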