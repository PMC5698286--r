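# Two-layer random-forest analysis: activity classification, frequency
# regression, per-fold importance with SEM, and exhaustive subset selection
# over the top-ranked features.

#' Assign genes to cross-validation folds
#'
#' @param ids gene ids (or an integer count).
#' @param k number of folds (default 10: 10% of genes per test set, every
#'   gene tested exactly once).
#' @param seed RNG seed.
#' @return integer fold vector named by gene id; fold sizes differ by at
#'   most one.
#' @export
make_folds <- function(ids, k = 10L, seed = 1L) {
  if (length(ids) == 1 && is.numeric(ids)) ids <- seq_len(ids)
  n <- length(ids)
  stopifnot(k >= 2L, n >= k)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  names(folds) <- ids
  folds
}

derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) * 2654435 + a * 40503 + b * 65537) %%
               2147483647)
}

#' Random-forest classifier of gene activity with cross-validated metrics
#'
#' Fits one forest per fold on the training genes and predicts the held-out
#' genes; metrics are pooled over all out-of-fold predictions. Importance is
#' the per-fold mean decrease in Gini impurity, averaged across folds with
#' its standard error.
#'
#' @param features genes x features numeric matrix (scaled).
#' @param active logical response (TRUE = active).
#' @param folds fold assignment from [make_folds()].
#' @param n_trees trees per fold (default 1000, as in the headline model).
#' @param mtry features tried per split; `NULL` uses the implementation
#'   default `floor(sqrt(p))`.
#' @param seed master RNG seed (per-fold seeds are derived from it).
#' @return list of class `rfc_result`: `prediction` (per-gene out-of-fold),
#'   `accuracy`, `active_accuracy`, `inactive_accuracy` (percent), `f1`,
#'   `importance` (data.frame `feature`, `mean`, `sem`).
#' @export
rf_classifier <- function(features, active, folds, n_trees = 1000L,
                          mtry = NULL, seed = 1L) {
  stopifnot(nrow(features) == length(active),
            length(folds) == length(active))
  y <- factor(ifelse(active, "active", "inactive"),
              levels = c("inactive", "active"))
  k <- max(folds)
  pred <- factor(rep(NA, length(y)), levels = levels(y))
  imp <- matrix(NA_real_, nrow = ncol(features), ncol = k,
                dimnames = list(colnames(features), NULL))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) stop("single-class training fold")
    set.seed(derive_seed(seed, f))
    fit <- randomForest::randomForest(
      x = features[tr, , drop = FALSE], y = y[tr],
      ntree = n_trees,
      mtry = if (is.null(mtry)) max(floor(sqrt(ncol(features))), 1) else mtry)
    pred[!tr] <- stats::predict(fit, features[!tr, , drop = FALSE])
    imp[, f] <- randomForest::importance(fit)[, "MeanDecreaseGini"]
  }
  tp <- sum(pred == "active" & y == "active")
  fp <- sum(pred == "active" & y == "inactive")
  fn <- sum(pred == "inactive" & y == "active")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(list(
    prediction = stats::setNames(pred, rownames(features)),
    accuracy = 100 * mean(pred == y),
    active_accuracy = 100 * mean(pred[y == "active"] == "active"),
    inactive_accuracy = 100 * mean(pred[y == "inactive"] == "inactive"),
    f1 = if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0,
    importance = data.frame(feature = rownames(imp),
                            mean = rowMeans(imp),
                            sem = apply(imp, 1, stats::sd) / sqrt(k),
                            row.names = NULL)),
    class = "rfc_result")
}

#' Random-forest regression of log2 recombination frequency
#'
#' Active genes only; out-of-fold RMSE over all test sets, importance as the
#' per-fold increase in node purity averaged across folds with its SEM.
#'
#' @param features genes x features matrix (active genes).
#' @param log2_freq numeric response (log2-transformed median normalized
#'   frequency).
#' @param folds fold assignment.
#' @param n_trees trees per fold.
#' @param mtry `NULL` uses the implementation default `max(floor(p/3), 1)`.
#' @param seed master RNG seed.
#' @return list of class `rfr_result`: `prediction`, `rmse`, `importance`.
#' @export
rf_regressor <- function(features, log2_freq, folds, n_trees = 1000L,
                         mtry = NULL, seed = 1L) {
  stopifnot(nrow(features) == length(log2_freq), all(is.finite(log2_freq)))
  k <- max(folds)
  if (any(table(folds) < 2)) stop("fewer than 2 genes in a fold")
  pred <- rep(NA_real_, length(log2_freq))
  imp <- matrix(NA_real_, nrow = ncol(features), ncol = k,
                dimnames = list(colnames(features), NULL))
  for (f in seq_len(k)) {
    tr <- folds != f
    set.seed(derive_seed(seed, f))
    fit <- randomForest::randomForest(
      x = features[tr, , drop = FALSE], y = log2_freq[tr],
      ntree = n_trees,
      mtry = if (is.null(mtry)) max(floor(ncol(features) / 3), 1) else mtry)
    pred[!tr] <- stats::predict(fit, features[!tr, , drop = FALSE])
    imp[, f] <- randomForest::importance(fit)[, "IncNodePurity"]
  }
  structure(list(
    prediction = stats::setNames(pred, rownames(features)),
    rmse = sqrt(mean((pred - log2_freq)^2)),
    importance = data.frame(feature = rownames(imp),
                            mean = rowMeans(imp),
                            sem = apply(imp, 1, stats::sd) / sqrt(k),
                            row.names = NULL)),
    class = "rfr_result")
}

#' Enumerate all non-empty feature subsets
#'
#' @param top_k number of candidate features (<= 16).
#' @return integer vector of bit masks `1 .. 2^top_k - 1`.
#' @export
subset_masks <- function(top_k) {
  stopifnot(top_k >= 1, top_k <= 16)
  seq_len(2^top_k - 1L)
}

mask_features <- function(mask, features) {
  features[bitwAnd(mask, bitwShiftL(1L, seq_along(features) - 1L)) != 0L]
}

#' Build the subset-enumeration table for model selection
#'
#' Enumerates every non-empty subset of the candidate features as a 16-bit
#' mask string; [model_selection()] fills this table with cross-validated
#' metrics, one row per fitted model.
#'
#' @param top_features character vector of candidate features (length <= 16).
#' @return data.frame with `mask`, `n_features`, `includes_ric` and the
#'   `top_features` attribute.
#' @export
selection_table <- function(top_features) {
  masks <- subset_masks(length(top_features))
  res <- data.frame(
    mask = vapply(masks, function(m)
      paste(rev(as.integer(intToBits(m)[1:16])), collapse = ""), character(1)),
    n_features = vapply(masks, function(m)
      length(mask_features(m, top_features)), integer(1)))
  res$includes_ric <- vapply(masks, function(m)
    "ric_score" %in% mask_features(m, top_features), logical(1))
  attr(res, "top_features") <- top_features
  attr(res, "masks") <- masks
  class(res) <- c("model_selection", "data.frame")
  res
}

#' Exhaustive model selection over the top-ranked features
#'
#' Restricts to the `top_k` most important features of an initial
#' cross-validated model, then fits one cross-validated random forest per
#' non-empty feature subset (2^top_k - 1 models) and records its metric.
#'
#' @param features genes x features matrix.
#' @param response logical (classification) or numeric (regression).
#' @param task `"classify"` or `"regress"`.
#' @param top_k number of candidate features (16 in the headline analysis).
#' @param folds fold assignment (shared across subsets).
#' @param n_trees trees per fold; desk-scale default 100, set 1000 to match
#'   the headline models.
#' @param seed master seed; per-(subset, fold) forests get derived seeds.
#' @param initial_importance optional precomputed importance data.frame
#'   (`feature`, `mean`); when `NULL` an initial all-features model is fitted.
#' @return data.frame of class `model_selection`: `mask` (16-bit string),
#'   `n_features`, metric columns (`accuracy`/`f1` or `rmse`),
#'   `includes_ric`, plus attribute `top_features`.
#' @export
model_selection <- function(features, response, task = c("classify", "regress"),
                            top_k = 16L, folds = NULL, n_trees = 100L,
                            seed = 1L, initial_importance = NULL) {
  task <- match.arg(task)
  if (is.null(folds)) folds <- make_folds(rownames(features), seed = seed)
  if (is.null(initial_importance)) {
    init <- if (task == "classify") {
      rf_classifier(features, response, folds, n_trees = max(n_trees, 500L),
                    seed = derive_seed(seed, 0L))
    } else {
      rf_regressor(features, response, folds, n_trees = max(n_trees, 500L),
                   seed = derive_seed(seed, 0L))
    }
    initial_importance <- init$importance
  }
  top <- initial_importance$feature[
    order(initial_importance$mean, decreasing = TRUE)][seq_len(top_k)]
  res <- selection_table(top)
  masks <- attr(res, "masks")
  metric1 <- numeric(length(masks))
  metric2 <- numeric(length(masks))
  for (mi in seq_along(masks)) {
    sel <- mask_features(masks[mi], top)
    sub <- features[, sel, drop = FALSE]
    if (task == "classify") {
      fit <- rf_classifier(sub, response, folds, n_trees = n_trees,
                           seed = derive_seed(seed, masks[mi], 1L))
      metric1[mi] <- fit$accuracy
      metric2[mi] <- fit$f1
    } else {
      fit <- rf_regressor(sub, response, folds, n_trees = n_trees,
                          seed = derive_seed(seed, masks[mi], 1L))
      metric1[mi] <- fit$rmse
    }
  }
  if (task == "classify") {
    res$accuracy <- metric1
    res$f1 <- metric2
  } else {
    res$rmse <- metric1
  }
  res
}

#' Convert a log2-scale RMSE to a fold prediction error
#'
#' On a log2-transformed response an RMSE of `x` corresponds to a `2^x`-fold
#' typical difference between predicted and observed frequency.
#'
#' @param rmse RMSE on the log2 scale.
#' @return fold error `2^rmse`.
#' @export
rmse_to_fold <- function(rmse) 2^rmse

#' Per-feature inclusion frequency among well-performing subsets
#'
#' Among the subsets passing the metric filter (and, optionally, the
#' RIC-inclusion filter), the fraction that contain each candidate feature.
#'
#' @param table a [model_selection()] result.
#' @param metric metric column to filter on (`"rmse"` or `"accuracy"`).
#' @param threshold keep subsets with metric strictly below (`rmse`) or above
#'   (`accuracy`) this value; `NULL` keeps all.
#' @param includes_ric `TRUE`/`FALSE` to restrict to subsets with/without the
#'   RIC score, `NULL` for no restriction.
#' @return named numeric vector of inclusion frequencies per feature.
#' @export
inclusion_frequency <- function(table, metric = "rmse", threshold = NULL,
                                includes_ric = NULL) {
  top <- attr(table, "top_features")
  keep <- rep(TRUE, nrow(table))
  if (!is.null(threshold)) {
    keep <- if (metric == "rmse") table[[metric]] < threshold
            else table[[metric]] > threshold
  }
  if (!is.null(includes_ric)) keep <- keep & table$includes_ric == includes_ric
  sub <- table[keep, , drop = FALSE]
  bits <- strsplit(sub$mask, "")
  # bit j of the mask (feature j) is character 17 - j of the bit string
  freq <- vapply(seq_along(top), function(j)
    mean(vapply(bits, function(b) b[17 - j] == "1", logical(1))), numeric(1))
  names(freq) <- top
  freq
}
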