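test_that("event counting respects strand and half-open window boundaries", {
  genes <- toy_genes()[1:2, ]          # gF forward, gR reverse
  w <- gene_windows(genes)
  ev <- data.frame(
    replicate = 1L, j_id = "J1", umi = "AAAAAA", junction = "x",
    v_start = c(9850L, 10599L, 10600L, 9849L, 9900L),
    v_strand = c("+", "+", "+", "+", "-"))
  cnt <- count_events(ev, genes, w)
  gf <- cnt$count[cnt$gene == "gF"]
  # window [9850, 10600): start in, last in, end out, before-start out;
  # opposite-strand event not counted
  expect_equal(sum(gf), 2)
  expect_equal(sum(cnt$count[cnt$gene == "gR"]), 0)  # gR window [10000,10750) "-"
})

test_that("events in overlapping count windows are counted in both", {
  genes <- data.frame(id = c("a", "b"), start = c(1000L, 1400L),
                      end = c(2000L, 2400L), strand = "+")
  ev <- data.frame(replicate = 1L, j_id = "J1", umi = "A", junction = "x",
                   v_start = 1900L, v_strand = "+")
  expect_message(cnt <- count_events(ev, genes), "overlapping")
  expect_equal(sum(cnt$count), 2)
})

test_that("replicate normalization scales to the median-total replicate", {
  counts <- expand.grid(gene = c("g1", "g2"), j = "J1", replicate = 1:3,
                        stringsAsFactors = FALSE)
  counts$count <- c(60, 40, 120, 80, 240, 160)   # totals 100, 200, 400
  norm <- normalize_replicates(counts, "all_J")
  expect_equal(unname(attr(norm, "scale_factors")), c(2, 1, 0.5))
  totals <- tapply(norm$normalized, norm$replicate, sum)
  expect_true(all(totals == 200))
  # identical replicates are unchanged
  same <- counts
  same$count <- rep(c(10, 20), 3)
  expect_equal(normalize_replicates(same, "all_J")$normalized, same$count)
})

test_that("with an even replicate count the lower-middle total is reference", {
  counts <- expand.grid(gene = "g1", j = "J1", replicate = 1:4,
                        stringsAsFactors = FALSE)
  counts$count <- c(100, 200, 300, 400)
  norm <- normalize_replicates(counts, "all_J")
  # hand computation: sorted totals (100,200,300,400) -> reference 200
  expect_equal(unname(attr(norm, "scale_factors")), c(2, 1, 2 / 3, 0.5))
  expect_error(normalize_replicates(transform(counts, count = c(0, 1, 2, 3)),
                                    "all_J"), "zero total")
})

test_that("J1-only scope computes totals from J1 rows alone", {
  counts <- expand.grid(gene = "g1", j = c("J1", "J2"), replicate = 1:3,
                        stringsAsFactors = FALSE)
  counts$count <- c(10, 999, 20, 999, 40, 999)
  norm <- normalize_replicates(counts, "J1_only")
  expect_equal(unname(attr(norm, "scale_factors")), c(2, 1, 0.5))
})

test_that("binomial activity p-values match the direct tail-sum oracle", {
  p <- 750 / 100000
  res <- binomial_activity_test(n = c(0, 120), N = 10000,
                                window_length = 750, v_region_length = 100000)
  expect_equal(res$p_value[1], 1)
  expect_false(res$active[1])
  expect_equal(res$p_value[2], oracle_binom_tail(120, 10000, p),
               tolerance = 1e-12)
  expect_error(binomial_activity_test(n = 11, N = 10,
                                      v_region_length = 1000),
               "exceeds")
})

test_that("binomial p-values are monotone decreasing in the count", {
  n <- 0:300
  res <- binomial_activity_test(n, N = 10000, window_length = 750,
                                v_region_length = 100000)
  expect_true(all(diff(res$p_value) <= 0))
})

test_that("a single fully-loaded gene gets the smallest adjusted p", {
  res <- binomial_activity_test(c(rep(0, 9), 50), N = 50,
                                window_length = 750, v_region_length = 100000)
  expect_equal(which.min(res$padj), 10)
  expect_equal(res$p_value[10], (750 / 100000)^50, tolerance = 1e-10)
  expect_true(res$active[10])
})

test_that("the mappability filter excludes duplicated genes, strict below", {
  loc0 <- simulate_locus(small_config())
  genes <- loc0$genes
  w <- loc0$windows
  # duplicate the mappability windows of genes 2 and 5 elsewhere
  dup <- data.frame(src = c(w$mapp_start[2], w$mapp_start[5]),
                    dest = c(92000L, 95000L), len = 400L)
  cfg2 <- small_config(planted_duplications = dup)
  loc <- simulate_locus(cfg2)
  kept <- apply_mappability_filter(loc$genes, loc$reference,
                                   windows = loc$windows)
  expect_setequal(setdiff(loc$genes$id, kept$id), loc$genes$id[c(2, 5)])
  oracle_mp <- vapply(seq_len(nrow(loc$genes)), function(g)
    oracle_mappability(loc$reference, loc$windows$mapp_start[g],
                       loc$windows$mapp_end[g], 85), numeric(1))
  expect_setequal(kept$id, loc$genes$id[oracle_mp >= 70])
  # retained at exactly the threshold: strict "below" semantics
  pristine <- apply_mappability_filter(loc0$genes, loc0$reference,
                                       windows = w, threshold = 100)
  expect_equal(nrow(pristine), nrow(loc0$genes))
})

test_that("activity calls on deep synthetic data recover planted truth", {
  cfg <- sim_config(seed = 17L, n_genes = 60L, locus_length = 280000L,
                    n_events = 30000L, chimaera_rate = 0,
                    pcr_duplicate_rate = 0, unrecombined_fraction = 0)
  loc <- simulate_locus(cfg)
  rd <- simulate_reads(loc)
  pr <- process_reads(rd$read1, rd$read2, rd$labels$replicate, loc$jgenes,
                      loc$reference, cfg$anchor_sequences)
  cnt <- count_events(pr$events, loc$genes, loc$windows)
  norm <- normalize_replicates(cnt, "J1_only")
  calls <- call_active_genes(norm, loc$v_region_length)
  truth <- loc$truth$active[match(calls$gene, loc$genes$id)]
  # FDR control: essentially no inactive gene called active
  expect_lte(sum(calls$active & !truth), ceiling(0.01 * sum(calls$active)))
  # sensitivity approaches 1 for genes sampled clearly above the window
  # background (the desk-scale locus is short, so the per-window background
  # expectation is non-trivial and weakly-used genes are undetectable)
  ord <- match(calls$gene, loc$genes$id)
  w <- ifelse(loc$truth$active, 2^loc$truth$log2_freq, 0)
  expected_j1 <- cfg$n_events * cfg$j_usage[["J1"]] * w / sum(w)
  detectable <- truth & expected_j1[ord] >= 60
  expect_gt(sum(detectable), 5)
  expect_gte(mean(calls$active[detectable]), 0.95)
})

test_that("normalization preserves within-replicate rank order", {
  loc <- simulate_locus(small_config())
  rd <- simulate_reads(loc)
  cfg <- small_config()
  pr <- process_reads(rd$read1, rd$read2, rd$labels$replicate, loc$jgenes,
                      loc$reference, cfg$anchor_sequences)
  cnt <- count_events(pr$events, loc$genes, loc$windows)
  norm <- normalize_replicates(cnt, "all_J")
  for (r in unique(norm$replicate)) {
    sub <- norm[norm$replicate == r, ]
    expect_equal(order(sub$count), order(sub$normalized))
  }
})
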