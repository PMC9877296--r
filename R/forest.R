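#' Classifier configuration
#'
#' Hyperparameters of the random-forest classifier used by the scoring and
#' modeling components. Defaults follow the conventional random-forest
#' settings for classification: 100 trees, `mtry = floor(sqrt(p))`,
#' unrestricted depth, nodes split down to single samples.
#'
#' @param trees Number of trees per forest.
#' @param mtry Features tried per split; `NULL` for `floor(sqrt(p))`.
#' @param min_node Minimum samples per leaf.
#' @param max_depth Maximum tree depth (safety cap; 25 is effectively
#'   unrestricted at pipeline sample sizes).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(trees = 100L, mtry = NULL, min_node = 1L,
                              max_depth = 25L) {
  stopifnot(trees >= 1L, min_node >= 1L, max_depth >= 1L)
  structure(list(trees = as.integer(trees),
                 mtry = if (is.null(mtry)) 0L else as.integer(mtry),
                 min_node = as.integer(min_node),
                 max_depth = as.integer(max_depth)),
            class = "classifier_config")
}

#' Fit a seeded random forest and predict class probabilities
#'
#' Trains a random forest (bootstrap-aggregated CART trees, gini splits,
#' random feature subsampling per split) on a training dataset and returns
#' the positive-class probability for every test sample: the average over
#' trees of the positive-class frequency in the leaf each test sample
#' reaches. Fully deterministic given the seed and independent of R's
#' global RNG state.
#'
#' @param train An [expression_dataset] used for fitting.
#' @param test An [expression_dataset] with the same features, to score.
#' @param cfg A [classifier_config].
#' @param seed Integer seed for bootstrap and split-feature sampling.
#' @return Numeric vector of P(pos) of length `nrow(test)`.
#' @export
rf_probability <- function(train, test, cfg = classifier_config(), seed = 1L) {
  if (!identical(train$feature_ids, test$feature_ids))
    stop("train and test datasets must share the same feature set and order")
  y <- as.integer(train$labels == "pos")
  if (all(y == 1L) || all(y == 0L))
    stop("training data must contain both classes")
  .rf_fit_predict(train$values, y, test$values, cfg$trees, cfg$mtry,
                  cfg$min_node, cfg$max_depth, as.double(seed))
}
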