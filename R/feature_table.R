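#' Construct a feature table
#'
#' The universal carrier between pipeline stages: a samples x features
#' abundance matrix with optional per-sample and per-feature metadata.
#' Values may be counts (16S ASV/taxon tables), RPK-scale gene abundances,
#' normalized expression, or log2-transformed values; the `value_kind` tag
#' records which, but is advisory and never enforced by arithmetic.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   All entries must be finite and non-negative.
#' @param sample_ids,feature_ids character vectors of unique ids; default to
#'   the dimnames of `values`.
#' @param sample_meta optional data.frame keyed by sample id (a `sample_id`
#'   column or rownames); typically carries `group` and `timepoint`.
#' @param feature_meta optional data.frame keyed by feature id; typically
#'   carries `taxon`, `family` (gene family / EC label) and `is_aars`.
#' @param value_kind one of `"count"`, `"rpk"`, `"normalized"`, `"log2"`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          feature_ids = colnames(values),
                          sample_meta = NULL, feature_meta = NULL,
                          value_kind = c("count", "rpk", "normalized", "log2")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)", call. = FALSE)
  if (length(feature_ids) != ncol(values))
    stop("length(feature_ids) must equal ncol(values)", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite value at sample '%s', feature '%s'",
                 sample_ids[bad[1, 1]], feature_ids[bad[1, 2]]),
         call. = FALSE)
  }
  # abundance-scale data must be non-negative; normalized/log2 expression
  # is legitimately signed
  if (value_kind %in% c("count", "rpk")) {
    neg <- which(values < 0, arr.ind = TRUE)
    if (nrow(neg) > 0)
      stop(sprintf("negative value at sample '%s', feature '%s'",
                   sample_ids[neg[1, 1]], feature_ids[neg[1, 2]]),
           call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  sample_meta <- .align_meta(sample_meta, sample_ids, "sample")
  feature_meta <- .align_meta(feature_meta, feature_ids, "feature")
  structure(
    list(values = values, sample_ids = sample_ids, feature_ids = feature_ids,
         sample_meta = sample_meta, feature_meta = feature_meta,
         value_kind = value_kind),
    class = "feature_table")
}

.align_meta <- function(meta, ids, what) {
  if (is.null(meta)) return(NULL)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  key <- paste0(what, "_id")
  if (key %in% names(meta)) {
    rownames(meta) <- meta[[key]]
    meta[[key]] <- NULL
  }
  missing <- setdiff(ids, rownames(meta))
  if (length(missing) > 0)
    stop(sprintf("%s metadata missing entries for: %s", what,
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  meta[ids, , drop = FALSE]
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features [%s]\n",
              length(x$sample_ids), length(x$feature_ids), x$value_kind))
  if (!is.null(x$sample_meta) && "group" %in% names(x$sample_meta)) {
    tab <- table(x$sample_meta$group)
    cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table by sample and/or feature ids
#'
#' @param x a `feature_table`.
#' @param samples,features character vectors of ids to keep (in the given
#'   order), or NULL to keep all.
#' @return a `feature_table` with metadata subset accordingly.
#' @export
ft_subset <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "feature_table"))
  if (is.null(samples)) samples <- x$sample_ids
  if (is.null(features)) features <- x$feature_ids
  missing_s <- setdiff(samples, x$sample_ids)
  if (length(missing_s) > 0)
    stop("unknown sample ids: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  missing_f <- setdiff(features, x$feature_ids)
  if (length(missing_f) > 0)
    stop("unknown feature ids: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  feature_table(x$values[samples, features, drop = FALSE],
                sample_ids = samples, feature_ids = features,
                sample_meta = if (!is.null(x$sample_meta))
                  x$sample_meta[samples, , drop = FALSE],
                feature_meta = if (!is.null(x$feature_meta))
                  x$feature_meta[features, , drop = FALSE],
                value_kind = x$value_kind)
}

#' Derive taxon labels from composite "gene|taxon" feature ids
#'
#' Per-organism gene tables conventionally use composite ids of the form
#' `"gene|taxon"` (HUMAnN3 style). When `feature_meta` lacks a taxon column
#' this splitter recovers the labels from the ids.
#'
#' @param feature_ids character vector of composite ids.
#' @return character vector of taxon labels (`NA` where no separator).
#' @export
split_taxon_labels <- function(feature_ids) {
  parts <- strsplit(as.character(feature_ids), "|", fixed = TRUE)
  vapply(parts, function(p) if (length(p) >= 2) p[length(p)] else NA_character_,
         character(1))
}

#' Read a feature table from TSV
#'
#' Expects a single header row of ids and one id column (first), with a
#' numeric body. Malformed input (ragged rows, duplicate ids, non-numeric or
#' negative cells, NA cells) raises a validation error naming the offending
#' row/column before any computation stage can consume the table.
#'
#' @param path TSV file path.
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`;
#'   the returned table is always samples x features.
#' @param value_kind tag recorded on the returned table.
#' @param sample_meta,feature_meta optional metadata passed through to
#'   [feature_table()].
#' @return a validated `feature_table`.
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_as_rows",
                                               "features_as_rows"),
                               value_kind = "count",
                               sample_meta = NULL, feature_meta = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1)
    stop(sprintf("ragged TSV: rows have %s fields",
                 paste(unique(nf), collapse = "/")), call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("TSV must have an id column and >=1 value column",
                          call. = FALSE)
  row_ids <- raw[[1]]
  col_ids <- colnames(raw)[-1]
  if (anyDuplicated(row_ids))
    stop("duplicate row ids: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(col_ids))
    stop("duplicate column ids: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "),
         call. = FALSE)
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                 row_ids[bad[1, 1]], col_ids[bad[1, 2]]), call. = FALSE)
  if (value_kind %in% c("count", "rpk")) {
    neg <- which(num < 0, arr.ind = TRUE)
    if (nrow(neg) > 0)
      stop(sprintf("negative value at row '%s', column '%s'",
                   row_ids[neg[1, 1]], col_ids[neg[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "features_as_rows") num <- t(num)
  feature_table(num, sample_meta = sample_meta, feature_meta = feature_meta,
                value_kind = value_kind)
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]: samples in rows, one `sample_id`
#' header column, full double precision.
#'
#' @param x a `feature_table`.
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(sample_id = x$sample_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a group design
#'
#' Maps each sample id to exactly one group label (e.g. control / dss3 /
#' dss6). Any label set is accepted; group-wise operations additionally
#' require at least two samples per compared group.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param groups character vector of group labels, one per sample.
#' @return a named character vector of class `group_design`.
#' @export
group_design <- function(sample_ids, groups) {
  sample_ids <- as.character(sample_ids)
  groups <- as.character(groups)
  if (length(sample_ids) != length(groups))
    stop("sample_ids and groups must have equal length", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("a sample may belong to exactly one group; duplicated: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(groups) || any(groups == ""))
    stop("every sample needs a non-empty group label", call. = FALSE)
  structure(stats::setNames(groups, sample_ids), class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  tab <- table(unclass(x))
  cat("group_design:",
      paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# samples of one group, in design order
design_samples <- function(design, group) {
  names(design)[unclass(design) == group]
}

# validates group presence / minimum size for two-group operations
check_two_groups <- function(design, group_a, group_b, min_n = 2) {
  for (g in c(group_a, group_b)) {
    n <- sum(unclass(design) == g)
    if (n == 0) stop("group not present in design: ", g, call. = FALSE)
    if (n < min_n)
      stop(sprintf("group '%s' has %d sample(s); >= %d required", g, n, min_n),
           call. = FALSE)
  }
  invisible(TRUE)
}
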