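#' Confusion-matrix metrics and AUC for a two-class score vector
#'
#' Thresholds the positive-class scores (`score >= threshold` predicts
#' `"pos"`) to obtain accuracy, sensitivity and specificity with `"pos"` as
#' the positive class; AUC is computed from the raw scores as the
#' Mann-Whitney pairwise-concordance statistic (tied pos/neg score pairs
#' count 1/2), so it is invariant under any strictly monotone transform of
#' the scores.
#'
#' @param labels Character vector of `"pos"`/`"neg"` truth labels.
#' @param scores Numeric vector of positive-class scores, same length.
#' @param threshold Classification cutoff (default 0.5).
#' @return A list of class `binary_metrics` with elements `accuracy`,
#'   `sensitivity`, `specificity`, `auc`.
#' @export
binary_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  labels <- normalize_labels(labels)
  if (!has_both_classes(labels))
    stop("metrics need both classes in the truth labels")
  pos <- labels == "pos"
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  # Mann-Whitney AUC via midranks: equals concordant-pair counting with
  # half-credit for ties
  r <- rank(scores)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  structure(list(accuracy = (tp + tn) / length(labels),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 auc = auc),
            class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  sensitivity %.4f  specificity %.4f  auc %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' M component: cumulative top-k model evaluation
#'
#' For k = 1..`max_k`, pools the miRNAs of the k best-ranked disease groups
#' (the union, in rank order, intersected with the training features),
#' trains a fresh classifier on the training partition restricted to that
#' pool, scores the held-out test partition, and records the metric suite.
#' The feature-pool size is non-decreasing in k by construction.
#'
#' @param train Training partition ([expression_dataset]).
#' @param test Held-out test partition sharing `train`'s feature space.
#' @param ranked_groups A data.frame from [score_all_groups()] (columns
#'   `disease`, `score`, `rank`, ordered by rank then name).
#' @param groups The [group_table] supplying group membership.
#' @param max_k Largest number of groups to accumulate (default 10; capped
#'   at the number of ranked groups).
#' @param cfg A [classifier_config].
#' @param seed Integer seed; each k derives its own forest seed.
#' @param threshold Classification cutoff for the confusion matrix.
#' @return A data.frame with one row per k: `n_groups`, `n_mirnas`,
#'   `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @export
evaluate_cumulative <- function(train, test, ranked_groups, groups,
                                max_k = 10L, cfg = classifier_config(),
                                seed = 1L, threshold = 0.5) {
  stopifnot(inherits(groups, "group_table"), nrow(ranked_groups) >= 1L,
            max_k >= 1L)
  ks <- seq_len(min(as.integer(max_k), nrow(ranked_groups)))
  pool <- character(0L)
  out <- vector("list", length(ks))
  for (k in ks) {
    members <- intersect(groups$groups[[ranked_groups$disease[k]]],
                         train$feature_ids)
    pool <- union(pool, members)
    if (!length(pool)) stop("empty miRNA union at k = 1")
    prob <- rf_probability(subset_features(train, pool),
                           subset_features(test, pool),
                           cfg, derive_seed(seed, k))
    m <- binary_metrics(test$labels, prob, threshold)
    out[[k]] <- data.frame(n_groups = k, n_mirnas = length(pool),
                           accuracy = m$accuracy, sensitivity = m$sensitivity,
                           specificity = m$specificity, auc = m$auc)
  }
  do.call(rbind, out)
}
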