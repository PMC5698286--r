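# Small fixtures built in code.

small_config <- function(...) {
  sim_config(n_genes = 15L, locus_length = 100000L, n_events = 800L,
             n_replicates = 2L, n_random_a_segments = 5L, seed = 42L, ...)
}

# A handful of hand-placed genes for window arithmetic.
toy_genes <- function() {
  data.frame(id = c("gF", "gR", "gEdge"),
             start = c(10000L, 10000L, 100L),
             end = c(10600L, 10600L, 700L),
             strand = c("+", "-", "+"),
             family = "Vk1", pseudogene = FALSE,
             ric_score = -10, distance_to_j1 = 50000L)
}

# Independent uniform feature matrices for the random-forest unit tests.
sep_features <- function(n, p = 6, seed = 80) {
  set.seed(seed)
  matrix(runif(n * p), nrow = n,
         dimnames = list(sprintf("g%03d", 1:n),
                         c("ric_score", paste0("f", 2:p))))
}

random_genes <- function(n, locus_length, seed) {
  set.seed(seed)
  start <- sort(sample(seq(4000L, locus_length - 8000L, by = 2L), n))
  len <- sample(seq(400L, 650L, by = 2L), n, replace = TRUE)
  data.frame(id = sprintf("g%02d", seq_len(n)), start = start,
             end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE))
}
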