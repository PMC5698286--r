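test_that("simulation is byte-identical given the same config and seed", {
  cfg <- small_config()
  a <- simulate_locus(cfg)
  b <- simulate_locus(cfg)
  expect_identical(a, b)
  expect_identical(simulate_chromatin(a), simulate_chromatin(b))
  expect_identical(simulate_reads(a), simulate_reads(b))
})

test_that("genes are non-overlapping, mixed-strand, with a bimodal RIC mix", {
  loc <- simulate_locus(sim_config(seed = 3L))
  g <- loc$genes
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  expect_true(all(g$start < g$end))
  # reverse-strand fraction within the exact binomial 99% interval
  n <- nrow(g)
  ci <- qbinom(c(0.005, 0.995), n, 0.55) / n
  frac <- mean(g$strand == "-")
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  expect_gt(sum(g$ric_score < -38.81), 0)
  expect_gt(sum(g$ric_score > -38.81), 0)
})

test_that("threshold activity model with incapable RIC gives no events", {
  cfg <- small_config(
    ric_mixture = list(p_capable = 0, mean_capable = -12, sd_capable = 6,
                       mean_incapable = -60, sd_incapable = 2),
    activity_model = list(type = "threshold"))
  loc <- simulate_locus(cfg)
  expect_true(all(loc$genes$ric_score < -38.81))
  expect_false(any(loc$truth$active))
  rd <- simulate_reads(loc)
  # inactive genes emit no recombination reads: everything is unrecombined
  # (or a chimaera/PCR copy of an unrecombined fragment)
  expect_equal(sum(rd$labels$category == "event"), 0)
  expect_true(all(is.na(rd$labels$gene)))
  expect_true(all(rd$labels$unrecombined))
})

test_that("every read carries exactly one category label", {
  loc <- simulate_locus(small_config())
  rd <- simulate_reads(loc)
  expect_true(all(rd$labels$category %in%
                    c("event", "duplicate", "chimaera", "unrecombined")))
  expect_equal(length(rd$read1), nrow(rd$labels))
  expect_equal(length(rd$read2), nrow(rd$labels))
  # duplicates are identical records of their parent
  lab <- rd$labels[rd$labels$replicate == 1, ]
  dups <- lab[lab$duplicate, ]
  parents <- lab[!lab$duplicate, ]
  key <- function(d) paste(d$umi, d$j, d$v_start)
  expect_true(all(key(dups) %in% key(parents)))
})

test_that("chimaera and duplicate rates behave as configured", {
  cfg0 <- small_config(chimaera_rate = 0, pcr_duplicate_rate = 0)
  rd0 <- simulate_reads(simulate_locus(cfg0))
  expect_equal(sum(rd0$labels$chimaera), 0)
  expect_equal(sum(rd0$labels$duplicate), 0)

  cfg <- small_config(pcr_duplicate_rate = 0.5, unrecombined_fraction = 0,
                      chimaera_rate = 0, n_events = 1000L, n_replicates = 1L,
                      depth_multipliers = 1)
  rd <- simulate_reads(simulate_locus(cfg))
  n_parent <- sum(!rd$labels$duplicate)
  total <- nrow(rd$labels)
  # one Bernoulli(0.5) re-emission per parent: total ~ parents * 1.5
  ci <- n_parent + qbinom(c(0.005, 0.995), n_parent, 0.5)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
})

test_that("J usage among events tracks the configured J1-biased vector", {
  loc <- simulate_locus(sim_config(seed = 9L, n_events = 20000L,
                                   n_replicates = 1L, depth_multipliers = 1))
  rd <- simulate_reads(loc)
  ev <- rd$labels[rd$labels$category == "event", ]
  frac <- mean(ev$true_j == "J1")
  ci <- qbinom(c(0.005, 0.995), nrow(ev), 0.40) / nrow(ev)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  expect_gt(frac, 0.35)
})

test_that("a zero-mean track is all zero and Bg-only layouts are exchangeable", {
  cfg <- small_config()
  cfg$base_means["YY1"] <- 0
  loc <- simulate_locus(cfg)
  chrom <- simulate_chromatin(loc)
  expect_true(all(chrom$tracks$YY1$count == 0))

  cfg2 <- small_config(plant_segments = FALSE, latent_effect = 0,
                       pu1_bind_fold = 1)
  chrom2 <- simulate_chromatin(simulate_locus(cfg2))
  expect_true(all(chrom2$bin_states == "Bg"))
  ks <- suppressWarnings(
    ks.test(chrom2$tracks$CTCF$count, chrom2$tracks$PAX5$count))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted enhancer segment lifts the RSS window by the set fold", {
  cfg <- sim_config(seed = 21L)
  loc <- simulate_locus(cfg)
  chrom <- simulate_chromatin(loc)
  w <- loc$windows
  rss_fold <- function(g)
    relative_enrichment(chrom$tracks$PAX5, w$rss_start[g], w$rss_end[g])
  e_folds <- vapply(which(loc$truth$e_rss), rss_fold, numeric(1))
  bg_folds <- vapply(which(!loc$truth$e_rss), rss_fold, numeric(1))
  # expected fold of a planted window: multiplier x base / locus-wide mean
  # (the locus mean sits above background because of the planted segments)
  expected <- cfg$e_multipliers["PAX5"] * cfg$base_means["PAX5"] /
    mean(chrom$tracks$PAX5$count)
  expect_equal(median(e_folds), unname(expected), tolerance = 0.2)
  expect_gt(median(e_folds), 2 * median(bg_folds))
})

test_that("FASTQ round-trip preserves reads and names", {
  loc <- simulate_locus(small_config())
  rd <- simulate_reads(loc)
  f <- tempfile(fileext = ".fastq")
  write_fastq(rd$read1[1:50], f)
  back <- read_fastq(f)
  expect_identical(unname(back), unname(rd$read1[1:50]))
  expect_identical(names(back), names(rd$read1[1:50]))
})
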