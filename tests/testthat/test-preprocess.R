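test_that("ttest_statistics agrees with stats::t.test (Welch) per feature", {
  ds <- null_ds(7, 9, 12, seed = 3)
  st <- ttest_statistics(ds)
  for (j in seq_len(12)) {
    ref <- t.test(ds$values[ds$labels == "pos", j],
                  ds$values[ds$labels == "neg", j])
    expect_equal(st$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(st$p[j], ref$p.value, tolerance = 1e-12)
  }
})

test_that("constant and class-identical features rank last with t=0, p=1", {
  vals <- cbind(c(1, 2, 3, 4, 5, 6),            # informative-ish
                rep(4, 6),                      # constant everywhere
                c(1, 2, 3, 1, 2, 3))            # identical values per class
  ds <- make_ds(vals, c("pos", "pos", "pos", "neg", "neg", "neg"))
  st <- ttest_statistics(ds)
  expect_equal(st$t[2], 0)
  expect_equal(st$p[2], 1)
  expect_equal(st$t[3], 0)  # zero mean difference, equal variances
  kept <- ttest_rank_filter(ds, 1)
  expect_equal(kept$feature_ids, "f1")
})

test_that("ttest_rank_filter keeps everything when n_keep >= p", {
  ds <- null_ds(5, 5, 8, seed = 11)
  out <- ttest_rank_filter(ds, 100)
  expect_setequal(out$feature_ids, ds$feature_ids)
  expect_identical(out$labels, ds$labels)
  expect_error(ttest_rank_filter(ds, 0), "positive")
})

test_that("label swap negates t, preserves p and the selected set", {
  ds <- null_ds(6, 8, 20, seed = 21)
  swapped <- ds
  swapped$labels <- ifelse(ds$labels == "pos", "neg", "pos")
  a <- ttest_statistics(ds)
  b <- ttest_statistics(swapped)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_identical(ttest_rank_filter(ds, 5)$feature_ids,
                   ttest_rank_filter(swapped, 5)$feature_ids)
})

test_that("a 2-pooled-SD shifted feature among 99 nulls survives n_keep=10", {
  hits <- 0L
  for (rep in 1:100) {
    set.seed(1000 + rep)
    n <- 50
    vals <- matrix(rnorm(2 * n * 100), ncol = 100)
    vals[1:n, 1] <- vals[1:n, 1] + 2      # unit SD both classes -> pooled SD 1
    ds <- make_ds(exp(vals), c(rep("pos", n), rep("neg", n)))
    kept <- ttest_rank_filter(ds, 10)$feature_ids
    hits <- hits + ("f1" %in% kept)
  }
  expect_gte(hits, 95L)
})

test_that("undersample balances classes deterministically", {
  ds <- null_ds(20, 10, 4, seed = 2)
  out <- undersample(ds, seed = 77)
  expect_equal(as.integer(table(out$labels)[c("pos", "neg")]), c(10L, 10L))
  expect_true(all(out$sample_ids %in% ds$sample_ids))
  # all minority samples retained
  expect_setequal(out$sample_ids[out$labels == "neg"],
                  ds$sample_ids[ds$labels == "neg"])
  expect_identical(undersample(ds, 77)$sample_ids, out$sample_ids)
  expect_false(identical(undersample(ds, 78)$sample_ids, out$sample_ids))
  balanced <- null_ds(15, 15, 3, seed = 4)
  expect_identical(undersample(balanced, 1)$sample_ids, balanced$sample_ids)
})

test_that("stratified_split honours per-class round-half-up counts", {
  cases <- list(list(np = 10, nn = 10, frac = 0.7, train = c(7, 7)),
                list(np = 50, nn = 50, frac = 0.9, train = c(45, 45)),
                list(np = 15, nn = 5, frac = 0.5, train = c(8L, 3L)))
  for (cs in cases) {
    ds <- null_ds(cs$np, cs$nn, 3, seed = 6)
    sp <- stratified_split(ds, cs$frac, seed = 123)
    expect_equal(as.integer(table(ds$labels[sp$train])[c("pos", "neg")]),
                 cs$train)
    expect_setequal(c(sp$train, sp$test), seq_len(cs$np + cs$nn))
    expect_length(intersect(sp$train, sp$test), 0)
  }
})

test_that("stratified_split is seeded and rejects degenerate settings", {
  ds <- null_ds(8, 8, 3, seed = 9)
  expect_identical(stratified_split(ds, 0.7, 5)$train,
                   stratified_split(ds, 0.7, 5)$train)
  expect_error(stratified_split(ds, 1.2, 1), "in \\(0, 1\\)")
  tiny <- null_ds(2, 2, 3, seed = 10)
  expect_error(stratified_split(tiny, 0.9, 1), "without both classes")
})
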