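#' Order-statistic beta scores for robust rank aggregation
#'
#' Given an entity's normalized ranks across `L` ranked lists, sorted
#' ascending, the k-th beta score is the probability that the k-th order
#' statistic of L independent Uniform(0,1) ranks is at most the observed
#' value r(k): `beta_k = P(Binomial(L, r(k)) >= k)`. Small beta scores flag
#' an entity ranked better than chance in at least k lists. Computed via
#' the binomial tail, which is stable for L in the hundreds.
#'
#' @param normalized_ranks Numeric vector in (0, 1], sorted ascending, of
#'   length `L` (one normalized rank per list; absent entities carry 1).
#' @param L Number of lists aggregated. Defaults to
#'   `length(normalized_ranks)`.
#' @return Numeric vector of beta scores, same length as the input.
#' @export
beta_scores <- function(normalized_ranks, L = length(normalized_ranks)) {
  r <- as.numeric(normalized_ranks)
  if (length(r) != L) stop("need one normalized rank per list")
  if (any(r <= 0 | r > 1)) stop("normalized ranks must lie in (0, 1]")
  if (is.unsorted(r)) stop("normalized ranks must be sorted ascending")
  stats::pbinom(seq_along(r) - 1L, size = L, prob = r, lower.tail = FALSE)
}

#' Rho statistic and Bonferroni p-value for one entity
#'
#' The rho statistic is the minimum of the entity's beta scores; the
#' p-value applies a Bonferroni correction over the L order statistics
#' examined: `p = min(1, rho * L)`.
#'
#' @inheritParams beta_scores
#' @return A list with elements `rho` and `p_value`.
#' @export
rra_pvalue <- function(normalized_ranks, L = length(normalized_ranks)) {
  rho <- min(beta_scores(normalized_ranks, L))
  list(rho = rho, p_value = min(1, rho * L))
}

#' Aggregate ranked entity lists into a prioritized table
#'
#' Combines the per-iteration ranked lists (best entity first) produced by
#' repeated resampling into a single prioritization. Each entity's
#' normalized rank in list i is `position / |universe|` when present and 1
#' (worst) when absent — absence is informative, since resampling changes
#' which entities are rankable in a given iteration. Entities are scored
#' with [rra_pvalue()] over their L normalized ranks and returned sorted by
#' p-value ascending (ties broken by entity name), with a dense
#' `aggregate_rank`.
#'
#' @param lists A list of character vectors, each an ordered ranking (best
#'   first, unique entities) from one iteration.
#' @param universe Character vector of all eligible entity names; every
#'   listed entity must belong to it.
#' @return A data.frame with columns `entity`, `rho`, `p_value`,
#'   `aggregate_rank`.
#' @export
aggregate_rankings <- function(lists, universe) {
  if (!length(lists)) stop("need at least one ranked list")
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty entity universe")
  L <- length(lists)
  rank_mat <- matrix(1, nrow = length(universe), ncol = L,
                     dimnames = list(universe, NULL))
  for (i in seq_len(L)) {
    ent <- as.character(lists[[i]])
    if (anyDuplicated(ent)) stop("entities must be unique within a list")
    outside <- setdiff(ent, universe)
    if (length(outside))
      stop("entities outside the universe: ",
           paste(utils::head(outside, 5L), collapse = ", "))
    rank_mat[ent, i] <- seq_along(ent) / length(universe)
  }
  res <- apply(rank_mat, 1L, function(r) unlist(rra_pvalue(sort(r), L)))
  out <- data.frame(entity = universe, rho = res["rho", ],
                    p_value = res["p_value", ], stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$entity), , drop = FALSE]
  out$aggregate_rank <- match(out$p_value, sort(unique(out$p_value)))
  rownames(out) <- NULL
  out
}
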