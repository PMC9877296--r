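#' G component: build per-disease two-class sub-datasets
#'
#' For each disease group, extracts from the expression dataset the columns
#' for the group's member miRNAs (the intersection of members with the
#' dataset's features) while keeping every sample and its class label.
#' Groups whose intersection is smaller than `max(min_size, 1)` are dropped
#' with a message; overlapping groups are allowed and features are not
#' deduplicated across groups at this stage.
#'
#' @param ds An [expression_dataset].
#' @param groups A [group_table].
#' @param min_size Minimum intersected group size to keep (default 1: any
#'   non-empty intersection is scored).
#' @param quiet Suppress the dropped-group message?
#' @return Named list of [expression_dataset] objects, one per surviving
#'   group, in the group table's order.
#' @export
build_group_subdatasets <- function(ds, groups, min_size = 1L, quiet = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(groups, "group_table"))
  min_size <- max(as.integer(min_size), 1L)
  members <- lapply(groups$groups, intersect, ds$feature_ids)
  drop <- lengths(members) < min_size
  if (any(drop) && !quiet)
    message("dropping ", sum(drop), " group(s) with <", min_size,
            " member(s) present in the expression data")
  if (all(drop))
    stop("every group is empty after intersecting with the expression features")
  lapply(members[!drop], function(m) subset_features(ds, m))
}

#' Intersected group-size distribution
#'
#' Number of each group's member miRNAs present in the expression dataset,
#' reported for every group (including empty intersections), e.g. to plot
#' the group-size distribution of the prior knowledge against a dataset.
#'
#' @inheritParams build_group_subdatasets
#' @return Named integer vector of intersected sizes, one entry per group.
#' @export
group_size_distribution <- function(groups, ds) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(groups, "group_table"))
  vapply(groups$groups, function(m) length(intersect(m, ds$feature_ids)),
         integer(1L))
}
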