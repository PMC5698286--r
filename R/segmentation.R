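# Chromatin-state segmentation: a multivariate hidden Markov model with
# independent negative-binomial emissions per track, EM-fitted on 200-bp
# binned counts, with A/E/Bg state labelling and the gene-assignment rule.

#' Bin read positions or binned tracks into a count matrix
#'
#' @param tracks named list; each element is either a numeric vector of read
#'   positions (0-based) or a binned data.frame (`start`, `end`, `count`)
#'   whose bins match `bin_width`.
#' @param locus_length locus length; the last partial bin is dropped.
#' @param bin_width bin width in bp (default 200).
#' @return integer matrix, tracks x bins.
#' @export
bin_counts <- function(tracks, locus_length, bin_width = 200L) {
  n_bins <- locus_length %/% bin_width
  X <- matrix(0L, nrow = length(tracks), ncol = n_bins,
              dimnames = list(names(tracks), NULL))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (is.data.frame(tr)) {
      stopifnot(all(tr$end - tr$start == bin_width),
                all(tr$start %% bin_width == 0))
      idx <- tr$start %/% bin_width + 1L
      keep <- idx <= n_bins
      X[i, idx[keep]] <- as.integer(tr$count[keep])
    } else {
      b <- floor(tr / bin_width) + 1L
      tab <- table(b[b <= n_bins])
      X[i, as.integer(names(tab))] <- as.integer(tab)
    }
  }
  X
}

nb_loglik_matrix <- function(X, mu, size) {
  K <- nrow(mu)
  ll <- matrix(0, nrow = K, ncol = ncol(X))
  for (k in seq_len(K)) {
    for (i in seq_len(nrow(X))) {
      ll[k, ] <- ll[k, ] + stats::dnbinom(X[i, ], size = size[k, i],
                                          mu = mu[k, i], log = TRUE)
    }
  }
  ll
}

#' Fit a negative-binomial hidden Markov model to binned counts
#'
#' Independent negative-binomial emissions per track and state; parameters
#' estimated by EM (scaled forward-backward). State means are updated to the
#' posterior-weighted means and dispersions by one-dimensional maximization
#' of the expected complete-data log-likelihood, so the observed-data
#' log-likelihood is non-decreasing across iterations. Initialization is
#' seeded k-means on log1p counts.
#'
#' @param X tracks x bins count matrix.
#' @param K number of states (default 3).
#' @param seed RNG seed for the k-means initialization.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood increment.
#' @return object of class `nbhmm`: `K`, `mu` (K x tracks), `size`,
#'   `trans`, `init`, `loglik` (per-iteration trace), `converged`.
#' @export
fit_hmm <- function(X, K = 3L, seed = 1L, max_iter = 100L, tol = 1e-4) {
  stopifnot(K >= 1L, ncol(X) >= 1L)
  Tn <- ncol(X)
  D <- nrow(X)
  if (all(X == 0)) {
    warning("all-zero count matrix: single-state fallback")
    K <- 1L
  }
  set.seed(seed)
  if (K == 1L) {
    cl <- rep(1L, Tn)
  } else {
    cl <- stats::kmeans(t(log1p(X)), centers = K, nstart = 5L,
                        iter.max = 50L)$cluster
  }
  mu <- matrix(0, K, D, dimnames = list(NULL, rownames(X)))
  size <- matrix(10, K, D)
  for (k in seq_len(K)) {
    mu[k, ] <- pmax(rowMeans(X[, cl == k, drop = FALSE]), 1e-6)
  }
  trans <- matrix(0.1 / max(K - 1, 1), K, K)
  diag(trans) <- if (K > 1) 0.9 else 1
  init <- rep(1 / K, K)

  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ll_emit <- nb_loglik_matrix(X, mu, size)
    cmax <- apply(ll_emit, 2, max)
    B <- exp(sweep(ll_emit, 2, cmax))   # scaled emission likelihoods

    alpha <- matrix(0, K, Tn)
    scale_c <- numeric(Tn)
    a <- init * B[, 1]
    scale_c[1] <- sum(a)
    alpha[, 1] <- a / scale_c[1]
    for (t in 2:Tn) {
      a <- (crossprod(trans, alpha[, t - 1])) * B[, t]
      scale_c[t] <- sum(a)
      alpha[, t] <- a / scale_c[t]
    }
    beta <- matrix(0, K, Tn)
    beta[, Tn] <- 1
    for (t in (Tn - 1):1) {
      b <- trans %*% (B[, t + 1] * beta[, t + 1])
      beta[, t] <- b / scale_c[t + 1]
    }
    gamma <- alpha * beta
    gamma <- sweep(gamma, 2, colSums(gamma), "/")
    ll <- sum(log(scale_c)) + sum(cmax)
    loglik <- c(loglik, ll)

    if (iter > 1 && abs(ll - loglik[iter - 1]) < tol) {
      converged <- TRUE
      break
    }

    # M-step
    if (K > 1) {
      xi_sum <- matrix(0, K, K)
      for (t in 1:(Tn - 1)) {
        x <- (alpha[, t] %o% (B[, t + 1] * beta[, t + 1])) * trans
        xi_sum <- xi_sum + x / sum(x)
      }
      trans <- xi_sum / rowSums(xi_sum)
      init <- gamma[, 1]
    }
    for (k in seq_len(K)) {
      wk <- gamma[k, ]
      sw <- sum(wk)
      for (i in seq_len(D)) {
        m <- sum(wk * X[i, ]) / sw
        mu[k, i] <- max(m, 1e-6)
        f <- function(ls) {
          sum(wk * stats::dnbinom(X[i, ], size = exp(ls), mu = mu[k, i],
                                  log = TRUE))
        }
        opt <- stats::optimize(f, interval = c(log(1e-3), log(1e5)),
                               maximum = TRUE)
        size[k, i] <- exp(opt$maximum)
      }
    }
  }
  structure(list(K = K, mu = mu, size = size, trans = trans, init = init,
                 loglik = loglik, converged = converged),
            class = "nbhmm")
}

#' Decode the state path
#'
#' @param model an `nbhmm` fit.
#' @param X tracks x bins count matrix.
#' @param method `"posterior"` (per-bin posterior maximum, the default) or
#'   `"viterbi"`. Ties break to the lowest state id.
#' @return integer vector of state ids per bin.
#' @export
decode_states <- function(model, X, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  K <- model$K
  Tn <- ncol(X)
  ll_emit <- nb_loglik_matrix(X, model$mu, model$size)
  if (Tn == 1L) {
    return(which.max(log(model$init) + ll_emit[, 1]))
  }
  if (method == "viterbi") {
    lt <- log(model$trans)
    delta <- matrix(-Inf, K, Tn)
    psi <- matrix(0L, K, Tn)
    delta[, 1] <- log(model$init) + ll_emit[, 1]
    for (t in 2:Tn) {
      for (k in seq_len(K)) {
        v <- delta[, t - 1] + lt[, k]
        psi[k, t] <- which.max(v)
        delta[k, t] <- v[psi[k, t]] + ll_emit[k, t]
      }
    }
    path <- integer(Tn)
    path[Tn] <- which.max(delta[, Tn])
    for (t in (Tn - 1):1) path[t] <- psi[path[t + 1], t + 1]
    return(path)
  }
  cmax <- apply(ll_emit, 2, max)
  B <- exp(sweep(ll_emit, 2, cmax))
  alpha <- matrix(0, K, Tn)
  scale_c <- numeric(Tn)
  a <- model$init * B[, 1]
  scale_c[1] <- sum(a)
  alpha[, 1] <- a / scale_c[1]
  for (t in 2:Tn) {
    a <- (crossprod(model$trans, alpha[, t - 1])) * B[, t]
    scale_c[t] <- sum(a)
    alpha[, t] <- a / scale_c[t]
  }
  beta <- matrix(0, K, Tn)
  beta[, Tn] <- 1
  for (t in (Tn - 1):1) {
    beta[, t] <- (model$trans %*% (B[, t + 1] * beta[, t + 1])) / scale_c[t + 1]
  }
  gamma <- alpha * beta
  apply(gamma, 2, which.max)
}

#' Label HMM states as Architectural, Enhancer or Background
#'
#' Emission means are scaled per track (divided by the across-state maximum);
#' the Architectural state maximizes the mean scaled emission over the
#' architectural tracks, the Enhancer state over the enhancer tracks, and the
#' remaining states are Background. If the same state wins both, the conflict
#' is flagged for manual resolution.
#'
#' @param model an `nbhmm` fit with track names on `mu` columns.
#' @param architectural,enhancer track name sets.
#' @return character vector of labels per state id, with attribute
#'   `conflict` (logical).
#' @export
label_states <- function(model, architectural = c("CTCF", "RAD21"),
                         enhancer = NULL) {
  trk <- colnames(model$mu)
  if (is.null(enhancer)) enhancer <- setdiff(trk, c(architectural, "H3K27me3"))
  scaled <- sweep(model$mu, 2, pmax(apply(model$mu, 2, max), 1e-12), "/")
  a_score <- rowMeans(scaled[, intersect(architectural, trk), drop = FALSE])
  e_score <- rowMeans(scaled[, intersect(enhancer, trk), drop = FALSE])
  labels <- rep("Bg", model$K)
  a_state <- which.max(a_score)
  e_state <- which.max(e_score)
  conflict <- model$K >= 2 && a_state == e_state
  if (conflict) {
    warning("architectural and enhancer scores pick the same state; ",
            "flagged for manual resolution")
    labels[a_state] <- "A"
  } else {
    labels[a_state] <- "A"
    labels[e_state] <- "E"
  }
  attr(labels, "conflict") <- conflict
  labels
}

#' Contiguous same-state segments from a decoded path
#'
#' @param path integer state path per bin.
#' @param labels state labels (from [label_states()]).
#' @param bin_width bin width in bp.
#' @return data.frame `start`, `end`, `state`, `label`.
#' @export
state_segments <- function(path, labels, bin_width = 200L) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts * bin_width, end = ends * bin_width,
             state = r$values, label = labels[r$values])
}

#' Assign chromatin states to gene promoters and RSSs
#'
#' An A or E segment is assigned to a gene's promoter (RSS) when it overlaps
#' the window from the gene centre to 500 bp upstream (downstream) of the
#' gene — with the exception that a segment that does not overlap the gene
#' start and whose centre is downstream of the gene centre is assigned to the
#' RSS but not the promoter, and vice versa. Genes with no qualifying segment
#' are Background; both labels qualifying gives `"A+E"`.
#'
#' @param segments data.frame `start`, `end`, `label` (only A/E rows used).
#' @param genes gene annotation data.frame.
#' @param windows optional precomputed [gene_windows()].
#' @return data.frame `id`, `promoter_state`, `rss_state`.
#' @export
assign_states_to_genes <- function(segments, genes, windows = NULL) {
  if (is.null(windows)) windows <- gene_windows(genes)
  seg <- segments[segments$label %in% c("A", "E"), , drop = FALSE]
  seg_centre <- (seg$start + seg$end) %/% 2L
  centre <- windows$centre
  fwd <- genes$strand == "+"
  start_site <- ifelse(fwd, genes$start, genes$end - 1L)  # 5' terminal base
  end3 <- ifelse(fwd, genes$end - 1L, genes$start)        # 3' terminal base
  out <- data.frame(id = genes$id, promoter_state = "Bg", rss_state = "Bg")
  collapse <- function(lab) {
    lab <- unique(lab)
    if (length(lab) == 0) "Bg" else if (length(lab) == 2) "A+E" else lab
  }
  for (g in seq_len(nrow(genes))) {
    pw <- c(windows$promoter_start[g], windows$promoter_end[g])
    rw <- c(windows$rss_start[g], windows$rss_end[g])
    ov_prom <- seg$start < pw[2] & seg$end > pw[1]
    ov_rss <- seg$start < rw[2] & seg$end > rw[1]
    ov_start <- seg$start <= start_site[g] & seg$end > start_site[g]
    ov_end <- seg$start <= end3[g] & seg$end > end3[g]
    rel <- if (fwd[g]) seg_centre - centre[g] else centre[g] - seg_centre
    # exception clause: off-start segments centred downstream belong to the
    # RSS only; off-end segments centred upstream belong to the promoter only
    prom_ok <- ov_prom & !(!ov_start & rel > 0)
    rss_ok <- ov_rss & !(!ov_end & rel < 0)
    out$promoter_state[g] <- collapse(seg$label[prom_ok])
    out$rss_state[g] <- collapse(seg$label[rss_ok])
  }
  out
}
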