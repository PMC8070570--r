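#' Construct and validate a feature table
#'
#' A feature table is the unit every analysis stage transforms: an integer
#' matrix of read counts with features in rows and samples in columns, both
#' carrying unique identifiers as dimnames.
#'
#' @param counts numeric matrix (features x samples) of non-negative integer
#'   counts with unique rownames (feature ids) and colnames (sample ids).
#' @param allow_empty allow a table with zero rows (e.g. after a filter that
#'   removed everything). Per-sample totals of zero are always allowed only
#'   when `allow_empty = TRUE`.
#' @return the validated integer matrix with class `feature_table`.
#' @export
feature_table <- function(counts, allow_empty = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("feature table needs feature ids (rownames) and sample ids (colnames)")
  if (!allow_empty && (nrow(counts) < 1L || ncol(counts) < 1L))
    stop("feature table must have at least one feature and one sample")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(counts)) stop("feature table contains missing values")
  if (any(counts < 0)) stop("negative count in feature table")
  if (any(counts != round(counts))) stop("non-integer count in feature table")
  storage.mode(counts) <- "integer"
  if (!allow_empty && any(colSums(counts) == 0L))
    stop("sample(s) with zero total reads: ",
         paste(colnames(counts)[colSums(counts) == 0L], collapse = ", "))
  class(counts) <- c("feature_table", class(counts))
  counts
}

#' Read a feature table from TSV
#'
#' Canonical dialect: UTF-8 tab-separated values, features in rows, first
#' column feature ids, header row sample ids, `#` lines ignored.
#'
#' @param path path to the TSV file.
#' @return a validated [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty feature table: ", path)
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ", paste(dup, collapse = ", "))
  num <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, colnames(df)[-1L]))
  if (anyNA(num)) stop("non-numeric count in ", path)
  if (any(num != round(num))) stop("non-integer count in ", path)
  feature_table(num)
}

#' Write a feature table as TSV
#'
#' Row and column order are emitted exactly as stored.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param id_column name of the leading id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, id_column = "feature_id") {
  df <- data.frame(rownames(table), unclass(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sample_totals <- function(table) colSums(table)
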