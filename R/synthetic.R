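#' Configuration for the synthetic expression + association generator
#'
#' Describes a two-class miRNA expression study with planted structure: a
#' set of differentially expressed (DE) miRNAs shifted between classes, a
#' few disease groups enriched for those DE miRNAs, and background groups
#' drawn from null miRNAs. Defaults describe the scale at which the
#' pipeline is exercised in tests: a balanced 60-sample cohort, 200
#' miRNAs of which 20 are DE with a 2-pooled-SD shift, and 5 enriched
#' groups (90% DE members) among 50.
#'
#' @param n_pos,n_neg Case/control sample counts.
#' @param n_features Total number of miRNA features.
#' @param n_de Number of differentially expressed miRNAs.
#' @param effect_size Between-class mean shift of DE miRNAs, in pooled-SD
#'   units of the log-scale signal.
#' @param n_groups Total number of disease groups.
#' @param n_enriched Number of groups drawn mostly from DE miRNAs.
#' @param group_size_range Length-2 integer vector, `(min, max)` members
#'   per group.
#' @param enrichment_purity Fraction of an enriched group's members sampled
#'   from the DE pool (the rest come from null miRNAs).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 30L, n_neg = 30L, n_features = 200L,
                             n_de = 20L, effect_size = 2,
                             n_groups = 50L, n_enriched = 5L,
                             group_size_range = c(4L, 20L),
                             enrichment_purity = 0.9, seed = 1L) {
  cfg <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              n_features = as.integer(n_features), n_de = as.integer(n_de),
              effect_size = as.numeric(effect_size),
              n_groups = as.integer(n_groups),
              n_enriched = as.integer(n_enriched),
              group_size_range = as.integer(group_size_range),
              enrichment_purity = as.numeric(enrichment_purity),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_pos >= 1L, n_neg >= 1L, n_features >= 1L,
              n_de >= 0L, n_de <= n_features,
              n_groups >= 1L, n_enriched >= 0L, n_enriched <= n_groups,
              length(group_size_range) == 2L,
              group_size_range[1L] >= 1L,
              group_size_range[1L] <= group_size_range[2L],
              enrichment_purity >= 0, enrichment_purity <= 1)
    if (group_size_range[2L] > n_features)
      stop("maximum group size exceeds the feature pool")
    if (n_enriched > 0L && ceiling(enrichment_purity * group_size_range[2L]) > n_de)
      stop("enriched groups may need up to ",
           ceiling(enrichment_purity * group_size_range[2L]),
           " DE members but only ", n_de, " DE miRNAs exist")
    if (group_size_range[2L] > n_features - n_de && n_de > 0L)
      stop("background groups cannot draw ", group_size_range[2L],
           " members from ", n_features - n_de, " null miRNAs")
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic expression dataset, group table and ground truth
#'
#' Expression is the exponential of a Gaussian log-signal (log-normal,
#' meanlog 3 / sdlog 1 — a smooth stand-in for RPM-normalized expression,
#' guaranteed non-negative). DE miRNAs receive a `+effect_size` pooled-SD
#' shift of the log-signal in the `"pos"` class. Group sizes are drawn from
#' a right-skewed (gamma) distribution truncated to `group_size_range`,
#' mimicking the skew of curated disease groups where most groups are
#' small and a few are large. Enriched groups draw
#' `ceiling(purity * size)` members from the DE pool and the rest from null
#' miRNAs; background groups draw only from null miRNAs.
#'
#' @param cfg A [synthetic_config].
#' @return A list with `dataset` (an [expression_dataset]), `groups` (a
#'   [group_table], group names `enriched_*` / `background_*`), and `truth`
#'   (list with `enriched_groups` and `de_mirnas`).
#' @export
synthetic_gsm <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_pos + cfg$n_neg
    labels <- c(rep("pos", cfg$n_pos), rep("neg", cfg$n_neg))
    feats <- sprintf("hsa-mir-s%04d", seq_len(cfg$n_features))
    de <- if (cfg$n_de > 0L) sort(sample(feats, cfg$n_de)) else character(0L)
    logsig <- matrix(stats::rnorm(n * cfg$n_features, mean = 3, sd = 1),
                     nrow = n, dimnames = list(sprintf("s%03d", seq_len(n)), feats))
    if (length(de))
      logsig[labels == "pos", de] <- logsig[labels == "pos", de] + cfg$effect_size
    ds <- expression_dataset(exp(logsig), labels)

    null_pool <- setdiff(feats, de)
    rng <- cfg$group_size_range
    draw_size <- function(k) {
      raw <- round(rng[1L] + stats::rgamma(k, shape = 1.5,
                                           scale = (rng[2L] - rng[1L]) / 3))
      pmin(pmax(raw, rng[1L]), rng[2L])
    }
    sizes <- draw_size(cfg$n_groups)
    grp <- vector("list", cfg$n_groups)
    names(grp) <- c(sprintf("enriched_%02d", seq_len(cfg$n_enriched)),
                    sprintf("background_%02d",
                            seq_len(cfg$n_groups - cfg$n_enriched)))
    for (g in seq_len(cfg$n_groups)) {
      if (g <= cfg$n_enriched) {
        n_de_members <- min(ceiling(cfg$enrichment_purity * sizes[g]), length(de))
        grp[[g]] <- c(sample(de, n_de_members),
                      sample(null_pool, sizes[g] - n_de_members))
      } else {
        grp[[g]] <- sample(null_pool, min(sizes[g], length(null_pool)))
      }
    }
    list(dataset = ds, groups = group_table(grp),
         truth = list(enriched_groups = names(grp)[seq_len(cfg$n_enriched)],
                      de_mirnas = de))
  })
}

#' Write a synthetic study to disk
#'
#' Serializes a [synthetic_gsm()] result in the exact dialects the readers
#' consume: `expression.tsv` (first column `sample`, `class` column,
#' feature columns), `associations.tsv` (two-column disease/miRNA pairs)
#' and `truth.tsv` (entity kind and name).
#'
#' @param sim A list from [synthetic_gsm()].
#' @param outdir Output directory, created if absent.
#' @return Invisibly, the named vector of paths written.
#' @export
write_synthetic <- function(sim, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(expression = file.path(outdir, "expression.tsv"),
             associations = file.path(outdir, "associations.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  ds <- sim$dataset
  expr <- data.frame(sample = ds$sample_ids, class = ds$labels,
                     ds$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, paths[["expression"]])
  assoc <- data.frame(
    disease = rep(names(sim$groups$groups), lengths(sim$groups$groups)),
    mirna = unlist(sim$groups$groups, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(assoc, paths[["associations"]])
  truth <- data.frame(
    kind = c(rep("enriched_group", length(sim$truth$enriched_groups)),
             rep("de_mirna", length(sim$truth$de_mirnas))),
    name = c(sim$truth$enriched_groups, sim$truth$de_mirnas),
    stringsAsFactors = FALSE)
  write_tsv(truth, paths[["truth"]])
  invisible(paths)
}
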