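#' Count aneuploid cells in a DI sample
#'
#' An aneuploid cell is one whose DNA index is at or above the threshold
#' (default 2.3, the British Columbia Cancer Agency criterion); the
#' comparison is inclusive, so a cell with DI exactly 2.3 counts.
#'
#' @param di_values non-empty numeric vector of positive DI values.
#' @param threshold positive DI cutoff, default 2.3.
#' @return Non-negative integer count.
#' @export
count_aneuploid <- function(di_values, threshold = 2.3) {
  di_values <- as.numeric(di_values)
  if (length(di_values) == 0L)
    stop("cannot count aneuploid cells in an empty DI sample", call. = FALSE)
  stopifnot(all(is.finite(di_values)), is.numeric(threshold),
            length(threshold) == 1L, threshold > 0)
  sum(di_values >= threshold)
}

#' Classify a case by the traditional aneuploidy rule
#'
#' The rule-based cytology call: `negative` with no aneuploid cell,
#' `atypical` with 1 to 5 (inclusive), `positive` with more than 5.
#' The three categories partition all non-negative counts.
#'
#' @param aneuploid_count non-negative integer (vectorised).
#' @return Character vector in `c("negative","atypical","positive")`.
#' @export
classify_traditional <- function(aneuploid_count) {
  aneuploid_count <- as.numeric(aneuploid_count)
  if (any(!is.finite(aneuploid_count)) || any(aneuploid_count < 0) ||
      any(aneuploid_count != floor(aneuploid_count)))
    stop("'aneuploid_count' must be non-negative integer(s)", call. = FALSE)
  ifelse(aneuploid_count == 0, "negative",
         ifelse(aneuploid_count <= 5, "atypical", "positive"))
}

#' Score a cohort with the traditional method
#'
#' Convenience wrapper applying [count_aneuploid()] and
#' [classify_traditional()] to every case.
#'
#' @param cases list of [case_record()] objects with non-empty DI values.
#' @param threshold DI cutoff passed to [count_aneuploid()].
#' @return `data.frame` with columns `case_id`, `aneuploid_count`,
#'   `category`.
#' @export
score_traditional <- function(cases, threshold = 2.3) {
  stopifnot(is.list(cases), all(vapply(cases, inherits, logical(1), "case_record")))
  counts <- vapply(cases, function(cs) count_aneuploid(cs$di_values, threshold),
                   numeric(1))
  data.frame(case_id = vapply(cases, `[[`, character(1), "case_id"),
             aneuploid_count = as.integer(counts),
             category = classify_traditional(counts))
}
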