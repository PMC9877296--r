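#' Construct a two-class miRNA expression dataset
#'
#' The central container of the package: a samples-by-miRNAs matrix of
#' non-negative, RPM-like normalized expression values together with a
#' two-class label per sample. Labels use the convention `"pos"` for
#' case/tumor samples and `"neg"` for control/normal samples.
#'
#' @param values Numeric matrix, samples in rows, miRNA features in columns.
#'   Row names are sample identifiers, column names miRNA names. Missing
#'   names are filled with `sample_1, ...` / the original column order.
#' @param labels Character vector of per-sample class labels, `"pos"` or
#'   `"neg"` (case-insensitive).
#' @param normalize_features Lowercase feature names (the package-wide miRNA
#'   identifier normalization)? Default `TRUE`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the matrix), `labels` (character vector aligned with rows),
#'   `sample_ids` and `feature_ids`.
#' @export
expression_dataset <- function(values, labels, normalize_features = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("expression values must have miRNA names as column names")
  if (normalize_features)
    colnames(values) <- normalize_mirna(colnames(values))
  labels <- normalize_labels(labels)
  if (length(labels) != nrow(values))
    stop("number of labels (", length(labels), ") does not match number of samples (",
         nrow(values), ")")
  if (anyNA(values))
    stop("expression values contain missing entries; filter rows before construction")
  if (any(values < 0))
    stop("expression values must be non-negative (RPM-like normalized expression)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers")
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicate miRNA features after normalization: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  structure(
    list(values = values, labels = labels,
         sample_ids = rownames(values), feature_ids = colnames(values)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("pos", "neg")))
  cat("expression_dataset: ", length(x$sample_ids), " samples (",
      tab[["pos"]], " pos / ", tab[["neg"]], " neg), ",
      length(x$feature_ids), " miRNAs\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Normalize miRNA identifiers
#'
#' Association databases and expression matrices mix identifier casings for
#' the same mature/precursor name (e.g. `hsa-miR-126` vs `hsa-mir-126`).
#' Normalization lowercases the whole token and trims surrounding
#' whitespace; paralogs with distinct suffixes (`hsa-mir-125b-1` vs
#' `hsa-mir-125b`) remain distinct.
#'
#' @param x Character vector of miRNA names.
#' @return Character vector of normalized names.
#' @export
normalize_mirna <- function(x) tolower(trimws(x))

# Map raw labels to pos/neg, erroring on anything unrecognized.
normalize_labels <- function(labels) {
  labels <- tolower(trimws(as.character(labels)))
  bad <- setdiff(unique(labels), c("pos", "neg"))
  if (length(bad))
    stop("unrecognized class labels: ", paste(bad, collapse = ", "),
         " (expected 'pos'/'neg'; remap other encodings at read time)")
  labels
}

# Subset helpers used throughout the pipeline ---------------------------------

# Restrict a dataset to a subset of samples (by index) keeping all metadata
# aligned. Internal: inputs are already validated.
subset_samples <- function(ds, idx) {
  structure(
    list(values = ds$values[idx, , drop = FALSE],
         labels = ds$labels[idx],
         sample_ids = ds$sample_ids[idx],
         feature_ids = ds$feature_ids),
    class = "expression_dataset")
}

# Restrict a dataset to named features, in the given order.
subset_features <- function(ds, features) {
  stopifnot(all(features %in% ds$feature_ids))
  structure(
    list(values = ds$values[, features, drop = FALSE],
         labels = ds$labels,
         sample_ids = ds$sample_ids,
         feature_ids = features),
    class = "expression_dataset")
}

# Both classes present?
has_both_classes <- function(labels) all(c("pos", "neg") %in% labels)

#' Construct a disease-group table
#'
#' Prior-knowledge container mapping each disease name to the set of miRNAs
#' experimentally associated with it. Members are deduplicated and
#' identifier-normalized; empty groups are rejected.
#'
#' @param groups Named list; each element a character vector of miRNA names
#'   for one disease.
#' @return An object of class `group_table`: list with `groups` (named list
#'   of normalized, deduplicated member vectors) and `t` (number of groups).
#' @export
group_table <- function(groups) {
  if (!length(groups)) stop("group table is empty")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("every group needs a disease name")
  if (anyDuplicated(names(groups)))
    stop("duplicate disease names in group table")
  groups <- lapply(groups, function(m) unique(normalize_mirna(m)))
  if (any(!lengths(groups)))
    stop("groups with no members: ",
         paste(names(groups)[!lengths(groups)], collapse = ", "))
  structure(list(groups = groups, t = length(groups)), class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  cat("group_table: ", x$t, " disease groups, member counts ",
      min(lengths(x$groups)), "-", max(lengths(x$groups)), "\n", sep = "")
  invisible(x)
}

# Seeding ----------------------------------------------------------------------

# Deterministic child-seed derivation: a counter-based affine map modulo the
# largest 31-bit prime, so derived seeds stay valid R integers and distinct
# counters give well-separated streams.
derive_seed <- function(seed, counter) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  as.integer(((s * 48271) %% m + as.double(counter) * 1000003) %% m)
}

# Evaluate expr with R's RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded internals never disturb the user session.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}
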