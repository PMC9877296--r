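# Shared fixture builders. All fixtures are built in code, seeded, and tiny.

# A dataset from an explicit matrix; features named f1..fp unless given.
make_ds <- function(values, labels, features = NULL) {
  values <- as.matrix(values)
  colnames(values) <- features %||% paste0("f", seq_len(ncol(values)))
  rownames(values) <- paste0("s", seq_len(nrow(values)))
  expression_dataset(values, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random null dataset: lognormal noise, balanced or given labels.
null_ds <- function(n_pos, n_neg, p, seed) {
  set.seed(seed)
  vals <- matrix(exp(rnorm((n_pos + n_neg) * p, 3, 1)), ncol = p)
  make_ds(vals, c(rep("pos", n_pos), rep("neg", n_neg)))
}

# Perfectly separable dataset on a single feature.
separable_ds <- function(n_per_class = 10, p_noise = 0, seed = 1) {
  set.seed(seed)
  sig <- c(rep(10, n_per_class), rep(0, n_per_class))
  vals <- cbind(sig, if (p_noise > 0)
    matrix(exp(rnorm(2 * n_per_class * p_noise, 3, 1)), ncol = p_noise))
  make_ds(vals, c(rep("pos", n_per_class), rep("neg", n_per_class)))
}

# The printed five-disease association fixture shipped with the package.
sample_assoc_path <- function() {
  system.file("extdata", "sample_associations.tsv", package = "gsmir",
              mustWork = TRUE)
}

# Write a dataset to the expression TSV dialect and return the path.
write_expression_fixture <- function(ds, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(sample = ds$sample_ids, class = ds$labels, ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Brute-force AUC oracle: concordant pos/neg pair counting with half-credit
# for ties. Kept deliberately naive and independent of the implementation.
auc_pair_oracle <- function(labels, scores) {
  pos <- scores[labels == "pos"]
  neg <- scores[labels == "neg"]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Exhaustive order-statistic oracle for the beta score: enumerate all 2^L
# hit patterns of L independent lists each beating rank r with prob r.
beta_tail_oracle <- function(r, k, L) {
  total <- 0
  for (mask in 0:(2^L - 1)) {
    hits <- sum(bitwAnd(mask, 2^(0:(L - 1))) > 0)
    if (hits >= k) total <- total + r^hits * (1 - r)^(L - hits)
  }
  total
}
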