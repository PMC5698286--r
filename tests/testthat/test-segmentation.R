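three_state_means <- function(n_tracks = 6, lo = 2, hi = 20) {
  means <- matrix(lo, 3, n_tracks,
                  dimnames = list(NULL, paste0("t", seq_len(n_tracks))))
  means[2, 1:2] <- hi                    # architectural-like
  means[3, 3:n_tracks] <- hi             # enhancer-like
  means
}

test_that("bin_counts tiles the locus and drops the partial bin", {
  x <- bin_counts(list(a = c(450)), locus_length = 1000, bin_width = 200)
  expect_equal(ncol(x), 5)
  expect_equal(x[1, ], c(0, 0, 1, 0, 0), ignore_attr = TRUE)
  # positions: total conserved minus reads in the dropped partial bin
  pos <- c(10, 250, 430, 990, 1130)
  x2 <- bin_counts(list(a = pos), locus_length = 1100, bin_width = 200)
  expect_equal(sum(x2), sum(pos < 1000))
  # binned data.frame input passes through
  tr <- data.frame(start = seq(0, 800, 200), end = seq(200, 1000, 200),
                   count = 1:5)
  expect_equal(bin_counts(list(a = tr), 1000)[1, ], 1:5, ignore_attr = TRUE)
})

test_that("K = 1 fit recovers empirical means with a unit transition matrix", {
  set.seed(60)
  X <- matrix(rpois(400, 7), nrow = 2)
  fit <- fit_hmm(X, K = 1, seed = 1)
  expect_equal(fit$trans, matrix(1, 1, 1))
  expect_equal(as.numeric(fit$mu), rowMeans(X), tolerance = 1e-6)
  expect_warning(f0 <- fit_hmm(matrix(0L, 2, 50), K = 3), "single-state")
  expect_equal(f0$K, 1)
})

test_that("EM recovers a planted 3-state path and improves monotonically", {
  trans <- matrix(0.05, 3, 3)
  diag(trans) <- 0.9
  sim <- simulate_state_tracks(three_state_means(), trans, n_bins = 1500,
                               size = 10, seed = 61)
  fit <- fit_hmm(sim$X, K = 3, seed = 2, max_iter = 60)
  expect_true(all(diff(fit$loglik) > -1e-6))
  post <- decode_states(fit, sim$X)
  expect_gte(best_permutation_accuracy(post, sim$states, 3), 0.95)
  vit <- decode_states(fit, sim$X, method = "viterbi")
  expect_gte(mean(post == vit), 0.90)
})

test_that("state labelling follows the architectural/enhancer emissions", {
  trans <- matrix(0.05, 3, 3)
  diag(trans) <- 0.9
  means <- three_state_means()
  colnames(means) <- c("CTCF", "RAD21", "PU.1", "PAX5", "IRF4", "MED1")
  sim <- simulate_state_tracks(means, trans, n_bins = 2000, size = 10,
                               seed = 62)
  fit <- fit_hmm(sim$X, K = 3, seed = 3)
  labels <- label_states(fit, architectural = c("CTCF", "RAD21"),
                         enhancer = c("PU.1", "PAX5", "IRF4", "MED1"))
  # the CTCF/RAD21-high state is A, the TF-high state is E, the rest Bg
  decoded <- decode_states(fit, sim$X)
  a_state <- which(labels == "A")
  e_state <- which(labels == "E")
  expect_gte(mean(sim$states[decoded == a_state] == 2), 0.9)
  expect_gte(mean(sim$states[decoded == e_state] == 3), 0.9)
  expect_equal(labels[which.min(rowSums(fit$mu))], "Bg")
  expect_false(attr(labels, "conflict"))
})

test_that("identical emissions across states are flagged as a conflict", {
  model <- structure(list(K = 2,
                          mu = matrix(5, 2, 4,
                                      dimnames = list(NULL, c("CTCF", "RAD21",
                                                              "PU.1", "PAX5"))),
                          size = matrix(10, 2, 4)), class = "nbhmm")
  expect_warning(lab <- label_states(model, architectural = c("CTCF", "RAD21"),
                                     enhancer = c("PU.1", "PAX5")),
                 "same state")
  expect_true(attr(lab, "conflict"))
})

test_that("gene-state assignment handles spanning segments and the exception", {
  gene <- data.frame(id = "g", start = 10000L, end = 10600L, strand = "+",
                     ric_score = -10, distance_to_j1 = 1000)
  # an A segment spanning the whole gene is assigned to both windows
  span <- data.frame(start = 9800, end = 11000, label = "A")
  got <- assign_states_to_genes(span, gene)
  expect_equal(got$promoter_state, "A")
  expect_equal(got$rss_state, "A")
  # E segment overlapping the promoter window but not the gene start, with
  # its centre downstream of the gene centre: RSS only (the exception)
  ex <- data.frame(start = 10200, end = 10650, label = "E")
  got2 <- assign_states_to_genes(ex, gene)
  expect_equal(got2$promoter_state, "Bg")
  expect_equal(got2$rss_state, "E")
  # mirrored exception: off-3'-end segment centred upstream, promoter only
  ex2 <- data.frame(start = 9950, end = 10400, label = "E")
  got3 <- assign_states_to_genes(ex2, gene)
  expect_equal(got3$promoter_state, "E")
  expect_equal(got3$rss_state, "Bg")
})

test_that("random segment layouts agree with the literal-rule oracle", {
  set.seed(70)
  for (rep in 1:25) {
    genes <- random_genes(8, 60000L, seed = 700 + rep)
    segs <- data.frame(
      start = sample.int(60000L, 40),
      label = sample(c("A", "E", "Bg"), 40, replace = TRUE))
    segs$end <- segs$start + sample(c(200, 400, 600, 1200, 2400), 40,
                                    replace = TRUE)
    got <- assign_states_to_genes(segs, genes)
    expect_identical(got, oracle_assign_states(segs, genes))
  }
})

test_that("assignments are invariant to hidden-state relabelling", {
  trans <- matrix(0.05, 3, 3)
  diag(trans) <- 0.9
  means <- three_state_means()
  colnames(means) <- c("CTCF", "RAD21", "PU.1", "PAX5", "IRF4", "MED1")
  sim <- simulate_state_tracks(means, trans, n_bins = 300, size = 10,
                               seed = 64)
  fit <- fit_hmm(sim$X, K = 3, seed = 4)
  labels <- label_states(fit, architectural = c("CTCF", "RAD21"),
                         enhancer = c("PU.1", "PAX5", "IRF4", "MED1"))
  path <- decode_states(fit, sim$X)
  genes <- random_genes(5, 300 * 200L, seed = 65)
  segs <- state_segments(path, labels)
  perm <- c(3L, 1L, 2L)
  segs_perm <- state_segments(perm[path], labels[order(perm)])
  expect_identical(assign_states_to_genes(segs, genes),
                   assign_states_to_genes(segs_perm, genes))
})
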