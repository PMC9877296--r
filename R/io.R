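#' Read a two-class miRNA expression table
#'
#' Parses a delimited text file with samples in rows: the first column holds
#' sample identifiers, one column (default `class`) holds the two-class
#' label, and every remaining column is a numeric miRNA feature. The
#' delimiter is auto-detected between tab and comma. Any sample row with a
#' missing value in a feature column is dropped (the missing-value filter
#' applied up front by the pipeline); miRNA names are lowercased.
#'
#' @param path Path to a TSV/CSV file.
#' @param label_field Name of the label column. Default `"class"`.
#' @param label_map Optional named character vector remapping raw labels to
#'   `"pos"`/`"neg"`, e.g. `c(tumor = "pos", normal = "neg")` for files that
#'   do not use the pos/neg convention.
#' @return An [expression_dataset].
#' @export
read_expression <- function(path, label_field = "class", label_map = NULL) {
  df <- read_delimited(path)
  if (ncol(df) < 3L)
    stop("expression table needs a sample-id column, a label column and ",
         "at least one feature column")
  if (!label_field %in% colnames(df))
    stop("label column '", label_field, "' not found in ", path)
  sample_ids <- as.character(df[[1L]])
  labels <- as.character(df[[label_field]])
  if (!is.null(label_map)) {
    names(label_map) <- tolower(names(label_map))
    hit <- tolower(labels) %in% names(label_map)
    labels[hit] <- unname(label_map[tolower(labels[hit])])
  }
  feat_cols <- setdiff(colnames(df)[-1L], label_field)
  vals <- suppressWarnings(
    vapply(df[feat_cols], function(col) as.numeric(as.character(col)),
           numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(sample_ids, feat_cols))
  keep <- !apply(vals, 1L, anyNA) & !is.na(labels)
  if (!any(keep))
    stop("no samples survive the missing-value filter in ", path)
  expression_dataset(vals[keep, , drop = FALSE], labels[keep])
}

#' Read disease to miRNA associations
#'
#' Accepts either a two-column delimited file (disease, miRNA; one
#' association per row, in the style of curated miRNA-disease databases) or
#' a GMT file (group name, description, then members). Format is chosen by
#' extension (`.gmt`) or by column count. Members are identifier-normalized
#' and deduplicated per disease.
#'
#' @param path Path to the association file.
#' @param header Does a two-column file carry a header row? Default `TRUE`
#'   when the first row does not look like an association (second field not
#'   matching a miRNA-like token), else `FALSE`; pass explicitly to override.
#' @return A [group_table].
#' @export
read_associations <- function(path, header = NULL) {
  if (!file.exists(path)) stop("cannot read ", path)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty association file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L))
      stop("malformed GMT row (need name, description, >=1 member)")
    grp <- lapply(parts, function(p) p[-(1:2)])
    names(grp) <- vapply(parts, `[[`, "", 1L)
    return(group_table(grp))
  }
  df <- read_delimited(path, header = FALSE)
  if (ncol(df) != 2L)
    stop("association file must have exactly two columns (disease, miRNA); got ",
         ncol(df))
  if (!nrow(df)) stop("empty association file: ", path)
  first <- as.character(unlist(df[1L, ]))
  if (is.null(header))
    header <- tolower(first[2L]) %in% c("mirna", "mir", "member") ||
      !grepl("(mir|let)-", first[2L], ignore.case = TRUE)
  if (header) df <- df[-1L, , drop = FALSE]
  if (!nrow(df)) stop("association file has a header but no rows: ", path)
  disease <- trimws(as.character(df[[1L]]))
  mirna <- trimws(as.character(df[[2L]]))
  if (any(!nzchar(disease)) || any(!nzchar(mirna)))
    stop("malformed association row with an empty field")
  group_table(split(mirna, factor(disease, levels = unique(disease))))
}

# Minimal delimited reader with tab/comma auto-detection, UTF-8.
read_delimited <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("cannot read ", path)
  probe <- readLines(path, n = 1L, warn = FALSE, encoding = "UTF-8")
  if (!length(probe)) stop("empty file: ", path)
  sep <- if (lengths(regmatches(probe, gregexpr("\t", probe))) >=
             lengths(regmatches(probe, gregexpr(",", probe, fixed = TRUE)))) "\t" else ","
  utils::read.table(path, sep = sep, header = header, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", encoding = "UTF-8",
                    na.strings = c("NA", ""))
}

#' Write pipeline result tables
#'
#' Serializes a result bundle from [run_gsm()] to headed TSV files with a
#' deterministic row order, so two runs with the same seed produce
#' byte-identical output:
#' \describe{
#'   \item{group_scores.tsv}{per-iteration disease scores: iteration,
#'     disease, score, rank.}
#'   \item{cumulative.tsv}{mean cumulative top-k performance in
#'     descending-k order: n_groups, n_mirnas, accuracy, sensitivity,
#'     specificity, auc.}
#'   \item{diseases_aggregated.tsv / mirnas_aggregated.tsv}{robust
#'     rank-aggregation output: entity, rho, p_value, aggregate_rank.}
#' }
#'
#' @param bundle Result list from [run_gsm()].
#' @param outdir Output directory, created if absent.
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_gsm_tables <- function(bundle, outdir) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, mode = 2L) != 0L)
    stop("output directory not writable: ", outdir)
  paths <- c(
    group_scores = file.path(outdir, "group_scores.tsv"),
    cumulative = file.path(outdir, "cumulative.tsv"),
    diseases = file.path(outdir, "diseases_aggregated.tsv"),
    mirnas = file.path(outdir, "mirnas_aggregated.tsv"))
  scores <- do.call(rbind, lapply(seq_along(bundle$iteration_scores), function(i)
    cbind(iteration = i, bundle$iteration_scores[[i]])))
  write_tsv(scores, paths[["group_scores"]])
  cum <- bundle$cumulative
  write_tsv(cum[order(-cum$n_groups), , drop = FALSE], paths[["cumulative"]])
  write_tsv(bundle$disease_aggregation, paths[["diseases"]])
  write_tsv(bundle$mirna_aggregation, paths[["mirnas"]])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
}
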