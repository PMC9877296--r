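#' Run the full Grouping-Scoring-Modeling pipeline
#'
#' Orchestrates the outer Monte-Carlo cross-validation around the G, S and
#' M components. Each outer iteration, with a seed derived deterministically
#' from `seed` and the iteration counter:
#' \enumerate{
#'   \item stratified 90/10 split into training and held-out test partitions;
#'   \item class balancing of the training partition by [undersample()];
#'   \item noise filtering of the balanced training partition by
#'     [ttest_rank_filter()] (top `n_keep` features); the surviving feature
#'     set is imposed on the test partition;
#'   \item G: per-disease sub-datasets ([build_group_subdatasets()]);
#'   \item S: group scoring and dense ranking ([score_all_groups()]) on the
#'     training partition only;
#'   \item M: cumulative top-k evaluation on the held-out test partition
#'     ([evaluate_cumulative()]).
#' }
#' The held-out partition of an iteration is touched only by the final
#' evaluation step. Iterations that degenerate (e.g. a partition losing a
#' class after balancing) are re-drawn with the next derived seed so that
#' exactly `outer_iters` iterations contribute to the averages. After the
#' loop, cumulative metrics are averaged per k, and the per-iteration
#' disease and miRNA orderings are combined by robust rank aggregation
#' ([aggregate_rankings()]).
#'
#' @param ds An [expression_dataset].
#' @param groups A [group_table].
#' @param outer_iters Number of outer Monte-Carlo iterations (100 at full
#'   scale; scale down for quick runs).
#' @param outer_train_frac Outer training fraction (default 0.9).
#' @param inner_reps,inner_train_frac Inner Monte-Carlo settings for group
#'   scoring (defaults 5 and 0.7).
#' @param n_keep Top differentially expressed features kept by the noise
#'   filter (default 1000).
#' @param max_k Number of top groups accumulated by the M component
#'   (default 10).
#' @param cfg A [classifier_config].
#' @param threshold Classification cutoff (default 0.5).
#' @param min_group_size Minimum intersected group size (default 1).
#' @param group_cap Optional integer m: truncate every group to its top-m
#'   members by the iteration's training-set t-test rank, equalizing group
#'   sizes. `NULL` (default) disables the cap.
#' @param seed Master seed; the run is fully reproducible given it.
#' @param verbose Emit one log line per iteration?
#' @return A list of class `gsm_result`: `iteration_scores` (list of score
#'   tables), `iteration_cumulative` (list of per-iteration cumulative
#'   tables), `cumulative` (per-k averages), `disease_aggregation`,
#'   `mirna_aggregation`, `mirna_lists` (per-iteration ranked miRNA lists),
#'   `splits` (per-iteration train/test sample ids), `log` (one row per
#'   iteration) and `params`.
#' @export
run_gsm <- function(ds, groups, outer_iters = 100L, outer_train_frac = 0.9,
                    inner_reps = 5L, inner_train_frac = 0.7,
                    n_keep = 1000L, max_k = 10L,
                    cfg = classifier_config(), threshold = 0.5,
                    min_group_size = 1L, group_cap = NULL, seed = 1L,
                    verbose = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(groups, "group_table"),
            outer_iters >= 1L)
  iter_scores <- iter_cum <- disease_lists <- mirna_lists <- splits <-
    vector("list", outer_iters)
  log <- vector("list", outer_iters)

  for (i in seq_len(outer_iters)) {
    res <- NULL
    for (attempt in seq_len(32L)) {
      s <- derive_seed(seed, (i - 1L) * 32L + attempt)
      res <- tryCatch(
        run_gsm_iteration(ds, groups, s, outer_train_frac, inner_reps,
                          inner_train_frac, n_keep, max_k, cfg, threshold,
                          min_group_size, group_cap),
        error = function(e) {
          if (verbose)
            message(sprintf("iteration %d attempt %d re-drawn: %s",
                            i, attempt, conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) break
    }
    if (is.null(res))
      stop("iteration ", i, " failed for 32 consecutive derived seeds; ",
           "the dataset is too small for the requested split settings")
    iter_scores[[i]] <- res$scores
    iter_cum[[i]] <- res$cumulative
    disease_lists[[i]] <- res$scores$disease
    mirna_lists[[i]] <- res$mirna_list
    splits[[i]] <- res$split_ids
    log[[i]] <- data.frame(
      iteration = i, seed = s, attempts = attempt,
      n_groups_scored = nrow(res$scores),
      top_group = res$scores$disease[1L],
      top_k_auc = res$cumulative$auc[nrow(res$cumulative)],
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf(
        "iteration %d: seed %d, %d groups scored, top '%s', k=%d AUC %.3f",
        i, s, nrow(res$scores), res$scores$disease[1L],
        nrow(res$cumulative), res$cumulative$auc[nrow(res$cumulative)]))
  }

  cum_all <- do.call(rbind, iter_cum)
  cumulative <- do.call(rbind, lapply(split(cum_all, cum_all$n_groups),
                                      function(d) {
    data.frame(n_groups = d$n_groups[1L], n_mirnas = mean(d$n_mirnas),
               accuracy = mean(d$accuracy), sensitivity = mean(d$sensitivity),
               specificity = mean(d$specificity), auc = mean(d$auc))
  }))
  cumulative <- cumulative[order(cumulative$n_groups), , drop = FALSE]
  rownames(cumulative) <- NULL

  mirna_universe <- sort(intersect(
    unique(unlist(groups$groups, use.names = FALSE)), ds$feature_ids))
  structure(list(
    iteration_scores = iter_scores,
    iteration_cumulative = iter_cum,
    cumulative = cumulative,
    disease_aggregation = aggregate_rankings(disease_lists,
                                             names(groups$groups)),
    mirna_aggregation = aggregate_rankings(mirna_lists, mirna_universe),
    mirna_lists = mirna_lists,
    splits = splits,
    log = do.call(rbind, log),
    params = list(outer_iters = outer_iters,
                  outer_train_frac = outer_train_frac,
                  inner_reps = inner_reps,
                  inner_train_frac = inner_train_frac, n_keep = n_keep,
                  max_k = max_k, cfg = cfg, threshold = threshold,
                  min_group_size = min_group_size, group_cap = group_cap,
                  seed = seed)),
    class = "gsm_result")
}

# One outer iteration: split, balance, filter, G, S, M, plus the ranked
# miRNA list used for aggregation. Internal.
run_gsm_iteration <- function(ds, groups, s, outer_train_frac, inner_reps,
                              inner_train_frac, n_keep, max_k, cfg,
                              threshold, min_group_size, group_cap) {
  sp <- stratified_split(ds, outer_train_frac, s)
  d_train <- undersample(subset_samples(ds, sp$train), derive_seed(s, 1L))
  d_train <- ttest_rank_filter(d_train, n_keep)
  d_test <- subset_features(subset_samples(ds, sp$test), d_train$feature_ids)

  groups_eff <- groups
  if (!is.null(group_cap)) {
    stopifnot(group_cap >= 1L)
    # d_train features are already in t-test rank order; keep each group's
    # top-m present members so every group contributes equally many miRNAs
    capped <- lapply(groups$groups, function(m) {
      present <- d_train$feature_ids[d_train$feature_ids %in% m]
      if (length(present)) utils::head(present, group_cap) else m
    })
    groups_eff <- group_table(capped)
  }

  scores <- score_all_groups(d_train, groups_eff, min_group_size, inner_reps,
                             inner_train_frac, cfg, derive_seed(s, 2L),
                             threshold)
  cumulative <- evaluate_cumulative(d_train, d_test, scores, groups_eff,
                                    max_k, cfg, derive_seed(s, 3L), threshold)

  list(scores = scores, cumulative = cumulative,
       mirna_list = rank_mirnas(scores, groups_eff, d_train$feature_ids,
                                max_k),
       split_ids = list(train = ds$sample_ids[sp$train],
                        test = ds$sample_ids[sp$test]))
}

#' Rank miRNAs by inherited group score
#'
#' Builds the per-iteration miRNA ranking that feeds rank aggregation: each
#' miRNA in the union of the top-`max_k` ranked groups inherits the best
#' (maximum) score among the top groups containing it, then miRNAs are
#' ordered by inherited score descending, name ascending.
#'
#' @param scores A ranked score table from [score_all_groups()].
#' @param groups The [group_table] supplying membership.
#' @param features Feature names of the training data (members outside it
#'   are ignored).
#' @param max_k Number of top groups whose members are ranked.
#' @return Character vector of miRNA names, best first.
#' @export
rank_mirnas <- function(scores, groups, features, max_k = 10L) {
  top <- utils::head(scores, min(as.integer(max_k), nrow(scores)))
  best <- numeric(0L)
  for (g in seq_len(nrow(top))) {
    members <- intersect(groups$groups[[top$disease[g]]], features)
    for (m in members)
      best[m] <- max(best[m], top$score[g], na.rm = TRUE)
  }
  if (!length(best)) return(character(0L))
  names(best)[order(-best, names(best))]
}
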