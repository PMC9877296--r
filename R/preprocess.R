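#' Welch t-test statistics for every feature
#'
#' Two-sided Welch (unequal-variance) t-test of pos vs neg for each miRNA.
#' Features that are constant within both classes carry no class signal and
#' are assigned `t = 0`, `p = 1` rather than an error, since real expression
#' matrices contain constant columns.
#'
#' @param ds An [expression_dataset] with at least two samples per class.
#' @return A data.frame with columns `feature`, `t`, `p`, one row per
#'   feature in dataset column order.
#' @export
ttest_statistics <- function(ds) {
  pos <- ds$labels == "pos"
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("Welch t-test needs at least two samples per class")
  x <- ds$values[pos, , drop = FALSE]
  y <- ds$values[!pos, , drop = FALSE]
  nx <- nrow(x); ny <- nrow(y)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- colSums(sweep(x, 2L, mx)^2) / (nx - 1)
  vy <- colSums(sweep(y, 2L, my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  dfree <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tstat), dfree, lower.tail = FALSE)
  flat <- se2 == 0
  tstat[flat] <- 0
  p[flat] <- 1
  data.frame(feature = ds$feature_ids, t = unname(tstat), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Noise filter: keep the top differentially expressed miRNAs
#'
#' Ranks features by two-sided Welch t-test p-value (ascending; ties broken
#' by |t| descending, then feature name) and keeps the first
#' `min(n_keep, #features)`. Applied to a training partition only; the
#' surviving feature set is then imposed on the matched test partition to
#' avoid information leaking from held-out samples.
#'
#' @param ds An [expression_dataset] with >= 2 samples per class.
#' @param n_keep Positive integer, number of features to retain
#'   (conventionally 1000).
#' @return The dataset restricted to the selected features, in rank order.
#' @export
ttest_rank_filter <- function(ds, n_keep = 1000L) {
  if (n_keep <= 0) stop("n_keep must be positive")
  st <- ttest_statistics(ds)
  ord <- order(st$p, -abs(st$t), st$feature)
  keep <- st$feature[ord][seq_len(min(as.integer(n_keep), nrow(st)))]
  subset_features(ds, keep)
}

#' Balance classes by random under-sampling
#'
#' Keeps the minority class intact and draws, uniformly without
#' replacement, an equally sized subset of the majority class. Sample order
#' of the original dataset is preserved.
#'
#' @param ds An [expression_dataset] with both classes present.
#' @param seed Integer seed; the selection is deterministic given the seed.
#' @return A class-balanced [expression_dataset] whose samples are a subset
#'   of the input samples.
#' @export
undersample <- function(ds, seed) {
  pos <- which(ds$labels == "pos")
  neg <- which(ds$labels == "neg")
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  n <- min(length(pos), length(neg))
  keep <- with_seed(seed, c(
    if (length(pos) > n) sample(pos, n) else pos,
    if (length(neg) > n) sample(neg, n) else neg))
  subset_samples(ds, sort(keep))
}

#' Stratified Monte-Carlo train/test split
#'
#' Draws, independently within each class, `round(train_frac * class size)`
#' samples (round half up, so class proportions in the training partition
#' match the dataset within rounding) for training; the remainder forms the
#' test partition.
#'
#' @param ds An [expression_dataset] with >= 2 samples per class.
#' @param train_frac Training fraction in (0, 1); 0.7 for the inner scoring
#'   splits, 0.9 for the outer evaluation splits.
#' @param seed Integer seed.
#' @return A list of class `split_spec`: `train` and `test` integer index
#'   vectors (sorted, disjoint, covering all samples) plus `seed`.
#' @export
stratified_split <- function(ds, train_frac, seed) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  idx_by_class <- split(seq_along(ds$labels), ds$labels)
  if (length(idx_by_class) < 2L || any(lengths(idx_by_class) < 2L))
    stop("stratified split needs >= 2 samples per class")
  train <- with_seed(seed, unlist(lapply(idx_by_class, function(idx) {
    n_train <- floor(train_frac * length(idx) + 0.5)  # round half up
    sample(idx, n_train)
  }), use.names = FALSE))
  test <- setdiff(seq_along(ds$labels), train)
  for (part in list(train, test))
    if (!has_both_classes(ds$labels[part]))
      stop("split leaves a partition without both classes; ",
           "use a less extreme train_frac or more samples")
  structure(list(train = sort(train), test = sort(test), seed = seed),
            class = "split_spec")
}
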