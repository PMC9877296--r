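#' S component: score one disease group by Monte-Carlo cross-validation
#'
#' The importance score of a disease group is the mean test-set
#' classification accuracy of the configured classifier over `inner_reps`
#' stratified Monte-Carlo train/test splits of the group's two-class
#' sub-dataset (70/30 by default, repeated five times). Each repetition
#' derives its own split and forest seed from `seed`, so the score is
#' deterministic.
#'
#' @param subds The group's two-class sub-dataset (an [expression_dataset]).
#' @param inner_reps Number of Monte-Carlo repetitions (default 5).
#' @param inner_train_frac Training fraction per repetition (default 0.7).
#' @param cfg A [classifier_config].
#' @param seed Integer seed.
#' @param threshold Probability cutoff mapping P(pos) to a predicted class.
#' @return Mean accuracy in `[0, 1]`.
#' @export
score_group <- function(subds, inner_reps = 5L, inner_train_frac = 0.7,
                        cfg = classifier_config(), seed = 1L,
                        threshold = 0.5) {
  acc <- vapply(seq_len(inner_reps), function(r) {
    rep_seed <- derive_seed(seed, r)
    sp <- stratified_split(subds, inner_train_frac, rep_seed)
    prob <- rf_probability(subset_samples(subds, sp$train),
                           subset_samples(subds, sp$test), cfg, rep_seed)
    truth <- subds$labels[sp$test] == "pos"
    mean((prob >= threshold) == truth)
  }, numeric(1L))
  mean(acc)
}

#' Score and dense-rank all disease groups
#'
#' Scores every group sub-dataset with [score_group()] and assigns dense
#' ranks: tied scores (compared after rounding to 4 decimals, the precision
#' at which scores are reported) share a rank, and rank values run
#' 1..#distinct scores with no gaps. Output rows are ordered by score
#' descending and, within ties, by disease name ascending — the order in
#' which the modeling component accumulates groups. Per-group seeds are
#' derived from the group's position in alphabetical name order, so the
#' result is invariant to the insertion order of the group table.
#'
#' @param train The (balanced, noise-filtered) training partition, an
#'   [expression_dataset].
#' @param groups A [group_table].
#' @param min_size Minimum intersected group size (see
#'   [build_group_subdatasets()]).
#' @param inner_reps,inner_train_frac,cfg,seed,threshold Passed to
#'   [score_group()].
#' @return A data.frame with columns `disease`, `score`, `rank`, ordered by
#'   rank then disease name.
#' @export
score_all_groups <- function(train, groups, min_size = 1L, inner_reps = 5L,
                             inner_train_frac = 0.7,
                             cfg = classifier_config(), seed = 1L,
                             threshold = 0.5) {
  subds <- build_group_subdatasets(train, groups, min_size, quiet = TRUE)
  if (!length(subds)) stop("no scorable groups")
  nm <- sort(names(subds))
  scores <- vapply(seq_along(nm), function(i) {
    score_group(subds[[nm[i]]], inner_reps, inner_train_frac, cfg,
                derive_seed(seed, i), threshold)
  }, numeric(1L))
  rank_group_scores(data.frame(disease = nm, score = scores,
                               stringsAsFactors = FALSE))
}

#' Dense-rank a table of group scores
#'
#' Applies the reporting convention for group scores: scores are compared
#' after rounding to 4 decimal places, equal scores share a rank, and ranks
#' are dense (1, 1, 2, ... with no gaps). Rows are returned ordered by
#' score descending, disease name ascending.
#'
#' @param df A data.frame with columns `disease` and `score`.
#' @return The same data.frame with a `rank` column added, reordered.
#' @export
rank_group_scores <- function(df) {
  stopifnot(all(c("disease", "score") %in% names(df)))
  rounded <- round(df$score, 4L)
  df$rank <- match(-rounded, sort(unique(-rounded)))
  df <- df[order(-rounded, df$disease), , drop = FALSE]
  rownames(df) <- NULL
  df
}
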