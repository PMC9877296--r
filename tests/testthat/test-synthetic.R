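test_that("generator bookkeeping matches the configuration", {
  cfg <- synthetic_config(n_pos = 12, n_neg = 8, n_features = 60, n_de = 10,
                          n_groups = 9, n_enriched = 3,
                          group_size_range = c(3, 8), seed = 3)
  sim <- synthetic_gsm(cfg)
  expect_equal(dim(sim$dataset), c(20L, 60L))
  expect_equal(sum(sim$dataset$labels == "pos"), 12L)
  expect_equal(sum(sim$dataset$labels == "neg"), 8L)
  expect_equal(sim$groups$t, 9L)
  expect_true(all(lengths(sim$groups$groups) >= 3 &
                    lengths(sim$groups$groups) <= 8))
  expect_true(all(sim$dataset$values >= 0))
  expect_length(sim$truth$de_mirnas, 10L)
  expect_length(sim$truth$enriched_groups, 3L)
})

test_that("truth sets are disjoint from background names and null features", {
  sim <- synthetic_gsm(synthetic_config(seed = 8))
  bg <- setdiff(names(sim$groups$groups), sim$truth$enriched_groups)
  expect_length(intersect(sim$truth$enriched_groups, bg), 0)
  null_feats <- setdiff(sim$dataset$feature_ids, sim$truth$de_mirnas)
  expect_length(intersect(sim$truth$de_mirnas, null_feats), 0)
  # background groups contain no DE miRNAs at all
  for (g in bg)
    expect_length(intersect(sim$groups$groups[[g]], sim$truth$de_mirnas), 0)
  # enriched groups are mostly DE members
  for (g in sim$truth$enriched_groups) {
    m <- sim$groups$groups[[g]]
    expect_gte(length(intersect(m, sim$truth$de_mirnas)) / length(m), 0.8)
  }
})

test_that("generation is deterministic and leaves the session RNG alone", {
  cfg <- synthetic_config(seed = 21)
  a <- synthetic_gsm(cfg)
  set.seed(999)
  before <- .Random.seed
  b <- synthetic_gsm(cfg)
  expect_identical(before, .Random.seed)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$groups, b$groups)
  expect_identical(a$truth, b$truth)
})

test_that("effect_size 0 is calibrated: ~5% of features reject at alpha 0.05", {
  sim <- synthetic_gsm(synthetic_config(
    n_pos = 30, n_neg = 30, n_features = 2000, n_de = 100, effect_size = 0,
    n_groups = 2, n_enriched = 0, group_size_range = c(4, 10), seed = 13))
  st <- ttest_statistics(sim$dataset)
  frac <- mean(st$p < 0.05)
  # binomial tolerance: 0.05 +/- 4 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(frac, 0.05 - 0.0195)
  expect_lt(frac, 0.05 + 0.0195)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synthetic_config(n_features = 10, n_de = 2,
                                enrichment_purity = 0.5,
                                group_size_range = c(4, 20)),
               "exceeds the feature pool")
  expect_error(synthetic_config(n_de = 5, enrichment_purity = 1,
                                group_size_range = c(4, 20)),
               "DE members")
  expect_error(synthetic_config(n_de = 190, n_features = 200,
                                group_size_range = c(4, 20)),
               "background groups")
})

test_that("write_synthetic round-trips through the readers", {
  sim <- synthetic_gsm(synthetic_config(
    n_pos = 6, n_neg = 6, n_features = 30, n_de = 8, n_groups = 4,
    n_enriched = 1, group_size_range = c(3, 6), seed = 30))
  paths <- write_synthetic(sim, tempfile())
  ds <- read_expression(paths[["expression"]])
  expect_equal(ds$values, sim$dataset$values, tolerance = 1e-10)
  expect_identical(ds$labels, sim$dataset$labels)
  gt <- read_associations(paths[["associations"]])
  expect_equal(lapply(gt$groups, sort)[sort(names(gt$groups))],
               lapply(sim$groups$groups, sort)[sort(names(sim$groups$groups))])
  truth <- read.delim(paths[["truth"]])
  expect_setequal(truth$name[truth$kind == "enriched_group"],
                  sim$truth$enriched_groups)
})
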