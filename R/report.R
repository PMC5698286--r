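# Descriptive and inferential statistics on the quantified repertoire:
# variance explained by the RIC score, state-activity association,
# frequency tertiles with feature comparisons, and replicate clustering.

#' Variance in gene usage explained by the RIC score
#'
#' Ordinary least squares of log2 recombination frequency on the RIC score
#' over active genes; returns the coefficient of determination.
#'
#' @param log2_freq log2 frequencies of active genes.
#' @param ric matching RIC scores.
#' @return list with `r_squared`, `slope`, `fit` (the `lm` object).
#' @export
ric_variance_explained <- function(log2_freq, ric) {
  fit <- stats::lm(log2_freq ~ ric)
  list(r_squared = summary(fit)$r.squared,
       slope = stats::coef(fit)[["ric"]],
       fit = fit)
}

#' Association between chromatin state and gene activity
#'
#' Two-by-two Fisher's exact test of (gene carries an A, E or A+E state at
#' its promoter or RSS vs Background only) against (active vs inactive).
#'
#' @param assignments [assign_states_to_genes()] result.
#' @param active logical activity per gene (same order).
#' @return list with `p_value`, `odds_ratio`, `table`.
#' @export
state_activity_association <- function(assignments, active) {
  stopifnot(nrow(assignments) == length(active))
  marked <- assignments$promoter_state != "Bg" | assignments$rss_state != "Bg"
  tab <- table(factor(marked, levels = c(TRUE, FALSE)),
               factor(active, levels = c(TRUE, FALSE)),
               dnn = c("state", "active"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty category in the state/activity table")
  }
  ft <- stats::fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Split good-RIC active genes into frequency tertiles
#'
#' Genes with a RIC score above the floor are split by frequency rank into
#' three near-equal groups (remainder genes allocated to the upper groups, so
#' 71 genes give groups of 23/24/24). When a feature matrix is supplied, each
#' feature is compared between the groups pairwise with two-sided Wilcoxon
#' rank-sum tests, Benjamini-Hochberg adjusted per feature family.
#'
#' @param frequency recombination frequencies (median normalized counts) of
#'   active genes.
#' @param ric matching RIC scores.
#' @param features optional genes x features matrix (same row order).
#' @param ric_floor RIC quality floor (default -14).
#' @return list with `group` (factor low/medium/high per eligible gene),
#'   `sizes`, `eligible` (logical over the input), and `tests` (data.frame
#'   `feature`, `comparison`, `p`, `padj`) when features are given.
#' @export
frequency_tertiles <- function(frequency, ric, features = NULL,
                               ric_floor = -14) {
  eligible <- ric > ric_floor
  f <- frequency[eligible]
  n <- length(f)
  stopifnot(n >= 3)
  base <- n %/% 3L
  rem <- n - 3L * base
  sizes <- base + c(0L, 0L, 0L)
  if (rem >= 1) sizes[3] <- sizes[3] + 1L
  if (rem == 2) sizes[2] <- sizes[2] + 1L
  grp <- rep(c("low", "medium", "high"), times = sizes)
  group <- factor(grp[rank(f, ties.method = "first")],
                  levels = c("low", "medium", "high"))
  out <- list(group = group,
              sizes = stats::setNames(as.integer(sizes),
                                      c("low", "medium", "high")),
              eligible = eligible)
  if (!is.null(features)) {
    fe <- features[eligible, , drop = FALSE]
    combos <- list(c("low", "medium"), c("low", "high"), c("medium", "high"))
    rows <- list()
    for (j in colnames(fe)) {
      p <- vapply(combos, function(cc)
        stats::wilcox.test(fe[group == cc[1], j], fe[group == cc[2], j],
                           exact = FALSE)$p.value, numeric(1))
      rows[[j]] <- data.frame(
        feature = j,
        comparison = vapply(combos, paste, character(1), collapse = "_vs_"),
        p = p, padj = stats::p.adjust(p, method = "BH"))
    }
    out$tests <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  out
}

#' Correlation and clustering of replicate repertoires
#'
#' Pearson correlations between the log2 repertoires of every replicate x J
#' combination, and average-linkage hierarchical clustering on `1 - r`.
#'
#' @param norm output of [normalize_replicates()] (long data.frame with
#'   `gene`, `j`, `replicate`, `normalized`).
#' @param pseudocount added before the log2 transform (default 1, so
#'   zero-count genes stay finite).
#' @return list with `cor` (correlation matrix), `hclust`, `log2_matrix`.
#' @export
repertoire_clustering <- function(norm, pseudocount = 1) {
  norm$column <- paste(norm$j, norm$replicate, sep = "_r")
  m <- stats::xtabs(normalized ~ gene + column, data = norm)
  lm2 <- log2(unclass(m) + pseudocount)
  r <- stats::cor(lm2, method = "pearson")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(cor = r, hclust = hc, log2_matrix = lm2)
}
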