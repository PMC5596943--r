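# Tabular readers/writers for every artifact the tool exchanges: data matrix,
# stratification, fuzzy membership, survival table, categorical metadata.
# TSV is canonical; the delimiter is configurable; files are UTF-8. Loading
# never reorders or drops records, and missing values are rejected at load.

#' Validate a numeric record-by-feature matrix
#'
#' Rows are records (patients/samples), columns are features (genes);
#' transpose before calling if your file is the other way around. All values
#' must be finite and the row/column ids unique.
#'
#' @param x Numeric matrix with row and column names.
#' @return The validated matrix, invisibly unchanged.
#' @export
as_data_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_stratkit("matrix_parse_error", "expected a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_stratkit("matrix_parse_error", "matrix needs record row ids and feature column ids")
  if (anyDuplicated(rownames(x)))
    stop_stratkit("duplicate_id_error", paste0(
      "duplicate record id(s): ",
      paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
  if (anyDuplicated(colnames(x)))
    stop_stratkit("duplicate_id_error", paste0(
      "duplicate feature id(s): ",
      paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop_stratkit("matrix_parse_error", sprintf(
      "non-finite value at record '%s', feature '%s'",
      rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  x
}

#' Read a record-by-feature matrix
#'
#' First row holds feature ids, first column record ids, body is numeric.
#' Any non-numeric or missing cell is an error naming the offending cell.
#'
#' @param path File path.
#' @param delimiter Field delimiter (default tab).
#' @param impute_missing If `TRUE`, `NA` cells are replaced by the per-feature
#'   mean instead of raising an error. Off by default: missing values are
#'   rejected, not imputed.
#' @return Validated numeric matrix (records x features).
#' @export
read_matrix <- function(path, delimiter = "\t", impute_missing = FALSE) {
  if (!file.exists(path)) stop_param(paste0("file not found: ", path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "", fileEncoding = "UTF-8")
  if (ncol(df) < 2L)
    stop_stratkit("matrix_parse_error", "matrix file needs an id column and at least one feature")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop_stratkit("duplicate_id_error", paste0(
      "duplicate record id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  body <- df[, -1L, drop = FALSE]
  feat <- colnames(body)
  vals <- suppressWarnings(
    vapply(body, function(col) as.numeric(as.character(col)), numeric(nrow(body))))
  if (nrow(body) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    if (impute_missing) {
      for (j in unique(bad[, 2L])) {
        col <- vals[, j]
        col[!is.finite(col)] <- mean(col[is.finite(col)])
        vals[, j] <- col
      }
    } else {
      stop_stratkit("matrix_parse_error", sprintf(
        "non-numeric or missing cell at record '%s', feature '%s'",
        ids[bad[1L, 1L]], feat[bad[1L, 2L]]))
    }
  }
  dimnames(vals) <- list(ids, feat)
  as_data_matrix(vals)
}

#' Write a record-by-feature matrix
#'
#' Canonical layout: header row `id<delim>feature ids`, then one row per
#' record. `write_matrix(read_matrix(f))` reproduces a canonicalized `f`.
#'
#' @param mat Numeric matrix (records x features).
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_matrix <- function(mat, path, delimiter = "\t") {
  mat <- as_data_matrix(mat)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(mat)), collapse = delimiter), con)
  body <- apply(mat, 1L, function(r)
    paste(sprintf("%.15g", r), collapse = delimiter))
  writeLines(paste(rownames(mat), body, sep = delimiter), con)
  invisible(path)
}

#' Read a stratification from a two-column (record_id, group) table
#'
#' Group order is first-appearance order; record order within a group follows
#' the file.
#'
#' @param path File path.
#' @param delimiter Field delimiter.
#' @param matrix Optional data matrix; record ids absent from it are an error.
#' @return A [stratification()].
#' @export
read_stratification <- function(path, delimiter = "\t", matrix = NULL) {
  if (!file.exists(path)) stop_param(paste0("file not found: ", path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "", fileEncoding = "UTF-8")
  if (ncol(df) < 2L)
    stop_stratkit("matrix_parse_error", "stratification file needs record_id and group columns")
  ids <- as.character(df[[1L]]); grp <- as.character(df[[2L]])
  .check_known(ids, matrix)
  groups <- split(ids, factor(grp, levels = unique(grp)))
  stratification(as.list(groups), provenance = paste0("file:", basename(path)))
}

#' Write a stratification as a two-column table
#' @param strat A `stratification`.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_stratification <- function(strat, path, delimiter = "\t") {
  stopifnot(inherits(strat, "stratification"))
  lab <- strat_labels(strat)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("record_id", "group"), collapse = delimiter), con)
  writeLines(paste(names(lab), lab, sep = delimiter), con)
  invisible(path)
}

#' Read a fuzzy membership table (record_id + one numeric column per cluster)
#' @inheritParams read_stratification
#' @param threshold Display threshold passed to [fuzzy_membership()];
#'   default `1/k`.
#' @return A [fuzzy_membership()].
#' @export
read_membership <- function(path, delimiter = "\t", matrix = NULL, threshold = NULL) {
  if (!file.exists(path)) stop_param(paste0("file not found: ", path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "", fileEncoding = "UTF-8")
  if (ncol(df) < 2L)
    stop_stratkit("matrix_parse_error", "membership file needs record_id and >=1 cluster column")
  ids <- as.character(df[[1L]])
  .check_known(ids, matrix)
  W <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(W) <- "double"
  if (any(!is.finite(W)))
    stop_stratkit("matrix_parse_error", "membership table has missing or non-numeric weights")
  if (any(W < 0 | W > 1))
    stop_stratkit("membership_range_error", "membership weights must lie in [0, 1]")
  rownames(W) <- ids
  if (is.null(threshold)) threshold <- 1 / ncol(W)
  fuzzy_membership(W, threshold = threshold)
}

#' Write a fuzzy membership table
#' @param membership A `fuzzy_membership`.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_membership <- function(membership, path, delimiter = "\t") {
  stopifnot(inherits(membership, "fuzzy_membership"))
  W <- membership$weights
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("record_id", colnames(W)), collapse = delimiter), con)
  body <- apply(W, 1L, function(r)
    paste(sprintf("%.15g", r), collapse = delimiter))
  writeLines(paste(rownames(W), body, sep = delimiter), con)
  invisible(path)
}

#' Read a survival table (record_id, time, event)
#'
#' `time` must be >= 0 in study time units; `event` is 1 if the event was
#' observed and 0 if the record was censored.
#'
#' @inheritParams read_stratification
#' @return `data.frame` with columns record_id, time, event.
#' @export
read_survival <- function(path, delimiter = "\t", matrix = NULL) {
  if (!file.exists(path)) stop_param(paste0("file not found: ", path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "", fileEncoding = "UTF-8")
  if (ncol(df) < 3L)
    stop_stratkit("matrix_parse_error", "survival file needs record_id, time, event columns")
  out <- data.frame(record_id = as.character(df[[1L]]),
                    time = as.numeric(df[[2L]]),
                    event = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  as_survival_table(out, matrix = matrix)
}

#' Validate a survival table
#' @param df `data.frame` with record_id, time, event columns.
#' @param matrix Optional data matrix for id checking.
#' @return The validated `data.frame`.
#' @export
as_survival_table <- function(df, matrix = NULL) {
  need <- c("record_id", "time", "event")
  if (!all(need %in% names(df)))
    stop_stratkit("matrix_parse_error", "survival table needs record_id, time, event")
  if (anyDuplicated(df$record_id))
    stop_stratkit("duplicate_id_error", "duplicate record ids in survival table")
  if (any(!is.finite(df$time)) || any(df$time < 0))
    stop_stratkit("matrix_parse_error", "survival times must be finite and >= 0")
  if (!all(df$event %in% c(0L, 1L)))
    stop_stratkit("matrix_parse_error", "event flags must be 0 (censored) or 1 (event)")
  .check_known(df$record_id, matrix)
  df[need]
}

#' Write a survival table
#' @param df Survival `data.frame` (record_id, time, event).
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_survival <- function(df, path, delimiter = "\t") {
  df <- as_survival_table(df)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("record_id", "time", "event"), collapse = delimiter), con)
  writeLines(paste(df$record_id, sprintf("%.15g", df$time),
                   df$event, sep = delimiter), con)
  invisible(path)
}

#' Read a categorical metadata table (record_id + named categorical columns)
#' @inheritParams read_stratification
#' @return `data.frame` with a record_id column and character attribute columns.
#' @export
read_categorical <- function(path, delimiter = "\t", matrix = NULL) {
  if (!file.exists(path)) stop_param(paste0("file not found: ", path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "", fileEncoding = "UTF-8",
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop_stratkit("matrix_parse_error", "categorical file needs record_id and >=1 attribute")
  names(df)[1L] <- "record_id"
  if (anyDuplicated(df$record_id))
    stop_stratkit("duplicate_id_error", "duplicate record ids in categorical table")
  .check_known(df$record_id, matrix)
  df
}

.check_known <- function(ids, matrix) {
  if (is.null(matrix)) return(invisible())
  unknown <- setdiff(ids, rownames(matrix))
  if (length(unknown) > 0L)
    stop_stratkit("unknown_record_error", paste0(
      "record id(s) not present in the data matrix: ",
      paste(utils::head(unknown, 5L), collapse = ", ")))
  invisible()
}
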