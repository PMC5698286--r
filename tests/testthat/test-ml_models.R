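test_that("folds partition the genes with near-equal sizes", {
  f <- make_folds(105, k = 10, seed = 1)
  expect_equal(length(f), 105)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  expect_setequal(unique(f), 1:10)
  expect_false(identical(make_folds(105, seed = 1), make_folds(105, seed = 2)))
})

test_that("a cleanly separable label is classified perfectly and ranks first", {
  x <- sep_features(100)
  y <- x[, "f2"] > 0.5
  res <- rf_classifier(x, y, make_folds(100, seed = 3), n_trees = 200,
                       seed = 4)
  expect_equal(res$accuracy, 100)
  expect_equal(res$f1, 1)
  top <- res$importance$feature[which.max(res$importance$mean)]
  expect_equal(top, "f2")
  # out-of-fold coverage: every gene predicted exactly once
  expect_false(any(is.na(res$prediction)))
  expect_equal(length(res$prediction), 100)
})

test_that("overall accuracy is the class-size-weighted mean of class rates", {
  x <- sep_features(90, seed = 81)
  set.seed(5)
  y <- x[, "f3"] + runif(90, 0, 0.6) > 0.8
  res <- rf_classifier(x, y, make_folds(90, seed = 6), n_trees = 100, seed = 7)
  weighted <- (res$active_accuracy * sum(y) +
                 res$inactive_accuracy * sum(!y)) / 90
  expect_equal(res$accuracy, weighted, tolerance = 1e-9)
})

test_that("permuted labels give chance-level accuracy", {
  x <- sep_features(60, seed = 82)
  y <- x[, "f2"] > 0.4            # 60/40-ish split
  hits <- integer(20)
  for (s in 1:20) {
    set.seed(s)
    yp <- sample(y)
    res <- rf_classifier(x, yp, make_folds(60, k = 5, seed = s),
                         n_trees = 60, seed = s)
    hits[s] <- round(res$accuracy * 60 / 100)
  }
  maj <- max(mean(y), 1 - mean(y))
  ci <- qbinom(c(0.005, 0.995), 60, maj)
  # mean over the permutation null sits inside the majority-rate interval
  expect_gte(mean(hits), ci[1] - 2)
  expect_lte(mean(hits), ci[2])
})

test_that("regression recovers a noiseless linear response", {
  x <- sep_features(100, seed = 83)
  y <- 3 * x[, "f4"]
  res <- rf_regressor(x[, c("f4", "f5"), drop = FALSE], y,
                      make_folds(100, seed = 8), n_trees = 500, seed = 9)
  expect_lte(res$rmse, 0.1 * diff(range(y)))
  expect_false(any(is.na(res$prediction)))
  # constant response: RMSE exactly zero (the forest warns about regressing
  # on a degenerate response, which is the point of the case)
  res0 <- suppressWarnings(
    rf_regressor(x, rep(2, 100), make_folds(100, seed = 10),
                 n_trees = 50, seed = 11))
  expect_equal(res0$rmse, 0)
})

test_that("a permuted response has RMSE at or above the response spread", {
  x <- sep_features(80, seed = 84)
  y <- 2 * x[, "f2"] + rnorm(80, 0, 0.1)
  set.seed(12)
  yp <- sample(y)
  res <- rf_regressor(x, yp, make_folds(80, seed = 13), n_trees = 200,
                      seed = 14)
  expect_gte(res$rmse, sd(y) * 0.95)
})

test_that("subset enumeration covers all non-empty combinations", {
  expect_equal(length(subset_masks(16)), 65535)
  expect_equal(length(subset_masks(3)), 7)
  tab <- selection_table(paste0("f", 1:16))
  expect_equal(nrow(tab), 65535)
  expect_equal(sum(tab$n_features == 1), 16)
  expect_equal(sum(tab$n_features == 16), 1)
  expect_equal(table(tab$n_features), table(rep(1:16, choose(16, 1:16))),
               ignore_attr = TRUE)
})

test_that("a top-3 sweep fits every subset and finds the causal one", {
  x <- sep_features(60, seed = 85)
  y <- 2 * x[, "f2"] + x[, "f3"] + rnorm(60, 0, 0.2)
  ms <- model_selection(x, y, task = "regress", top_k = 3,
                        folds = make_folds(60, k = 5, seed = 15),
                        n_trees = 100, seed = 16)
  expect_equal(nrow(ms), 7)
  expect_true(all(c("mask", "n_features", "rmse", "includes_ric") %in%
                    names(ms)))
  best <- best_subset_features(ms)
  expect_true(all(c("f2", "f3") %in% attr(ms, "top_features")))
  expect_true("f2" %in% best)
})

test_that("classification sweeps report accuracy and F1 per subset", {
  x <- sep_features(60, seed = 86)
  y <- x[, "ric_score"] > 0.5
  ms <- model_selection(x, y, task = "classify", top_k = 3,
                        folds = make_folds(60, k = 5, seed = 17),
                        n_trees = 60, seed = 18)
  expect_equal(nrow(ms), 7)
  expect_true(any(ms$includes_ric))
  expect_gte(max(ms$accuracy[ms$includes_ric]), max(ms$accuracy[!ms$includes_ric]))
})

test_that("RMSE converts to fold error as 2^x", {
  expect_equal(rmse_to_fold(0), 1)
  expect_equal(signif(rmse_to_fold(1.36), 3), 2.57)
  expect_equal(signif(rmse_to_fold(1.44), 3), 2.71)
})

test_that("inclusion frequency reduces to the combinatorial value when vacuous", {
  tab <- selection_table(c("ric_score", paste0("f", 2:16)))
  tab$rmse <- 1   # constant metric: a vacuous threshold admits every subset
  freq <- inclusion_frequency(tab, metric = "rmse", threshold = Inf)
  expect_equal(unname(freq), rep(2^15 / (2^16 - 1), 16), tolerance = 1e-12)
  # a filter admitting exactly one subset gives 0/1 frequencies
  tab$rmse[5000] <- 0
  one <- inclusion_frequency(tab, metric = "rmse", threshold = 0.5)
  expect_true(all(one %in% c(0, 1)))
  # RIC filter restricts the denominator
  with_ric <- inclusion_frequency(tab, metric = "rmse", threshold = Inf,
                                  includes_ric = TRUE)
  expect_equal(unname(with_ric["ric_score"]), 1)
})
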