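# Independent oracles: brute-force or closed-form reference implementations
# kept deliberately separate from the package's code paths.

# Upper-tail binomial P(X >= n) by direct pmf summation.
oracle_binom_tail <- function(n, N, p) {
  if (n <= 0) return(1)
  sum(stats::dbinom(n:N, size = N, prob = p))
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration: the sum
# of probabilities of all tables (with the observed margins) no more probable
# than the observed one, with the conventional (1 + 1e-7) slack.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}

# Brute-force window mappability: counts each k-mer's occurrences over both
# strands by plain substring enumeration.
oracle_mappability <- function(reference, start, end, k) {
  L <- nchar(reference)
  comp <- chartr("ACGT", "TGCA", reference)
  rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  all_starts <- 1:(L - k + 1)
  pool <- c(substring(reference, all_starts, all_starts + k - 1),
            substring(rc, all_starts, all_starts + k - 1))
  counts <- table(pool)
  s <- (max(start, 0):min(end - 1, L - k)) + 1
  kmers <- substring(reference, s, s + k - 1)
  100 * mean(as.integer(counts[kmers]) == 1L)
}

# Exhaustive substring search of a read on both strands; returns 0-based
# leftmost coordinates and strands of every exact hit.
oracle_search <- function(read, reference) {
  comp <- chartr("ACGT", "TGCA", read)
  rcread <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  hits <- data.frame(pos = integer(0), strand = character(0))
  f <- as.integer(gregexpr(read, reference, fixed = TRUE)[[1]])
  if (f[1] != -1) hits <- rbind(hits, data.frame(pos = f - 1L, strand = "+"))
  r <- as.integer(gregexpr(rcread, reference, fixed = TRUE)[[1]])
  if (r[1] != -1) hits <- rbind(hits, data.frame(pos = r - 1L, strand = "-"))
  hits
}

# Literal re-implementation of the promoter/RSS state-assignment rule,
# including the exception clause, as a plain double loop.
oracle_assign_states <- function(segments, genes) {
  out <- data.frame(id = genes$id, promoter_state = "Bg", rss_state = "Bg")
  for (g in seq_len(nrow(genes))) {
    fwd <- genes$strand[g] == "+"
    centre <- (genes$start[g] + genes$end[g]) %/% 2
    if (fwd) {
      prom <- c(genes$start[g] - 500, centre)
      rss <- c(centre, genes$end[g] + 500)
      start_base <- genes$start[g]
      end_base <- genes$end[g] - 1
    } else {
      prom <- c(centre, genes$end[g] + 500)
      rss <- c(genes$start[g] - 500, centre)
      start_base <- genes$end[g] - 1
      end_base <- genes$start[g]
    }
    prom_labels <- character(0)
    rss_labels <- character(0)
    for (i in seq_len(nrow(segments))) {
      lab <- segments$label[i]
      if (!lab %in% c("A", "E")) next
      a <- segments$start[i]
      b <- segments$end[i]
      sc <- (a + b) %/% 2
      downstream_of_centre <- if (fwd) sc > centre else sc < centre
      upstream_of_centre <- if (fwd) sc < centre else sc > centre
      covers_start <- a <= start_base && b > start_base
      covers_end <- a <= end_base && b > end_base
      if (a < prom[2] && b > prom[1]) {
        if (!(!covers_start && downstream_of_centre)) {
          prom_labels <- c(prom_labels, lab)
        }
      }
      if (a < rss[2] && b > rss[1]) {
        if (!(!covers_end && upstream_of_centre)) {
          rss_labels <- c(rss_labels, lab)
        }
      }
    }
    squash <- function(x) {
      x <- unique(x)
      if (length(x) == 0) "Bg" else if (length(x) == 2) "A+E" else x
    }
    out$promoter_state[g] <- squash(prom_labels)
    out$rss_state[g] <- squash(rss_labels)
  }
  out
}

# Best-permutation agreement between a decoded path and the true path.
best_permutation_accuracy <- function(path, truth, K) {
  perms <- if (K == 3) {
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  } else {
    stop("only K = 3 supported")
  }
  max(vapply(perms, function(p) mean(p[path] == truth), numeric(1)))
}

best_subset_features <- function(ms) {
  top <- attr(ms, "top_features")
  best <- ms$mask[which.min(ms$rmse)]
  bits <- rev(strsplit(best, "")[[1]])
  top[bits[seq_along(top)] == "1"]
}
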