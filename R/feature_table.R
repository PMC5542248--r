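#' Construct a peaks feature table
#'
#' The feature table is the reconstructed dataset the classifiers are
#' trained on: one row per case, ten integer columns `V1`..`V10` counting
#' the density peaks that fell into each ploidy interval, a `label` column
#' with the class factor (`c` = OSCC, `k` = OLK, `n` = normal, `u` =
#' unknown), and a `case_id` column.
#'
#' @param counts integer matrix (or data frame) with 10 columns of
#'   non-negative counts, one row per case.
#' @param label character vector of class labels in `c("c","k","n","u")`.
#' @param case_id character vector of unique case identifiers.
#' @return A `data.frame` of class `feature_table` with columns
#'   `V1..V10,label,case_id`.
#' @export
feature_table <- function(counts, label, case_id) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) counts <- matrix(integer(), ncol = 10L)
  if (ncol(counts) != 10L)
    stop("'counts' must have exactly 10 columns, got ", ncol(counts),
         call. = FALSE)
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0L))
    stop("interval counts must be non-negative integers", call. = FALSE)
  label <- as.character(label)
  if (!all(label %in% c("c", "k", "n", "u")))
    stop("labels must be one of 'c' (OSCC), 'k' (OLK), 'n' (normal), ",
         "'u' (unknown)", call. = FALSE)
  case_id <- as.character(case_id)
  if (anyDuplicated(case_id))
    stop("duplicate case_id in feature table: ",
         paste(unique(case_id[duplicated(case_id)]), collapse = ", "),
         call. = FALSE)
  stopifnot(nrow(counts) == length(label), length(label) == length(case_id))
  df <- as.data.frame(counts)
  names(df) <- paste0("V", 1:10)
  df$label <- label
  df$case_id <- case_id
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}

feature_counts <- function(table) {
  m <- as.matrix(as.data.frame(table)[, paste0("V", 1:10)])
  storage.mode(m) <- "integer"
  m
}

#' Write a feature table to CSV
#'
#' Emits the 12-column representation with header
#' `V1,...,V10,label,case_id`, preserving row order.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Reads a file written by [write_feature_table()] and re-checks all
#' invariants (12 columns, non-negative integer counts, unique case ids).
#'
#' @param path path to a 12-column feature CSV.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                        check.names = FALSE)
  expected <- c(paste0("V", 1:10), "label", "case_id")
  if (!identical(names(df), expected))
    stop("feature file ", path, " must have exactly the 12 columns ",
         paste(expected, collapse = ","), call. = FALSE)
  counts <- suppressWarnings(
    vapply(df[paste0("V", 1:10)], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) counts <- matrix(counts, nrow = 1L)
  if (nrow(df) == 0L) counts <- matrix(integer(), ncol = 10L)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("feature file ", path, " contains a negative or non-integer count",
         call. = FALSE)
  feature_table(counts, df$label, df$case_id)
}
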