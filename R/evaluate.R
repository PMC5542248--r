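#' Confusion matrix and binary classification metrics
#'
#' Tallies a 2x2 confusion matrix with the cancer class `c` as positive
#' and computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' positive predictive value `tp/(tp+fp)` and negative predictive value
#' `tn/(tn+fn)`. A metric whose denominator is zero is undefined and is
#' reported as `NA`, never as 0.
#'
#' @param truth,predicted equal-length non-empty character vectors with
#'   values in `c("c", "n")`.
#' @return Object of class `evaluation_report`: list with `confusion`
#'   (named counts `tp`, `fp`, `tn`, `fn`), the four metrics, and `auc`
#'   (`NA` until filled in, e.g. by [auc_rank()]).
#' @export
confusion_and_metrics <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) == 0L || length(truth) != length(predicted))
    stop("'truth' and 'predicted' must be non-empty and of equal length",
         call. = FALSE)
  if (!all(c(truth, predicted) %in% c("c", "n")))
    stop("labels must be 'c' (cancer) or 'n' (normal)", call. = FALSE)
  tp <- sum(truth == "c" & predicted == "c")
  fp <- sum(truth == "n" & predicted == "c")
  tn <- sum(truth == "n" & predicted == "n")
  fn <- sum(truth == "c" & predicted == "n")
  safe_div <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    auc = NA_real_), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n",
              cm[["tp"]], cm[["fp"]], cm[["tn"]], cm[["fn"]]))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat("sensitivity:", fmt(x$sensitivity), " specificity:", fmt(x$specificity),
      "\nppv:", fmt(x$ppv), " npv:", fmt(x$npv), " auc:", fmt(x$auc), "\n")
  invisible(x)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed by the rank formulation:
#' the probability that a randomly chosen cancer case scores above a
#' randomly chosen normal case, counting ties as one half.
#' `AUC = (R_c - n_c(n_c+1)/2) / (n_c n_n)` where `R_c` is the rank sum
#' of the cancer scores (midranks for ties).
#'
#' @param scores numeric risk scores (higher = more cancer-like).
#' @param truth character labels in `c("c", "n")`, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, truth) {
  scores <- as.numeric(scores); truth <- as.character(truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  if (!all(truth %in% c("c", "n")))
    stop("labels must be 'c' or 'n'", call. = FALSE)
  n_c <- sum(truth == "c"); n_n <- sum(truth == "n")
  if (n_c == 0L || n_n == 0L)
    stop("AUC is undefined with a single class present", call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[truth == "c"]) - n_c * (n_c + 1) / 2) / (n_c * n_n)
}

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop("expected a 2x2 table", call. = FALSE)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m)))
    stop("table entries must be non-negative integers", call. = FALSE)
  m
}

#' Build a follow-up contingency table
#'
#' The 2x2 table comparing malignant transformation between risk groups:
#' rows are risk groups (`high`, `low`), columns are outcomes
#' (`transformed`, `not_transformed`).
#'
#' @param risk character vector of per-case risk groups in
#'   `c("high", "low")`.
#' @param transformed logical vector: did the case transform during
#'   follow-up?
#' @return 2x2 integer matrix with dimnames.
#' @export
followup_table <- function(risk, transformed) {
  risk <- as.character(risk); transformed <- as.logical(transformed)
  stopifnot(length(risk) == length(transformed),
            all(risk %in% c("high", "low")), !any(is.na(transformed)))
  m <- matrix(0L, 2L, 2L,
              dimnames = list(risk = c("high", "low"),
                              outcome = c("transformed", "not_transformed")))
  for (g in c("high", "low")) {
    m[g, "transformed"] <- sum(risk == g & transformed)
    m[g, "not_transformed"] <- sum(risk == g & !transformed)
  }
  m
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Two-sided Pearson chi-square with the continuity correction
#' `sum( max(|O - E| - 0.5, 0)^2 / E )`, expected counts from the product
#' of marginals, 1 degree of freedom. The correction is clamped at
#' `|O - E|`, so a perfectly independent table yields statistic 0 and
#' p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts with all
#'   marginals positive.
#' @return List with `statistic`, `df` (always 1) and `p_value`.
#' @export
yates_chi_square <- function(table) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: every row and column total must be positive",
         call. = FALSE)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum(pmax(abs(m - E) - 0.5, 0)^2 / E)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Per-risk-group transformation percentages
#'
#' For each row of a follow-up table, the fraction of cases that
#' transformed, as a raw fraction and a percentage rounded to one
#' decimal.
#'
#' @param table 2x2 follow-up matrix (rows = risk groups, first column =
#'   transformed) with positive row totals.
#' @return `data.frame` with columns `group`, `transformed`, `total`,
#'   `fraction`, `percent` (one-decimal rounding).
#' @export
proportion_summary <- function(table) {
  m <- as_2x2(table)
  totals <- rowSums(m)
  if (any(totals == 0))
    stop("transformation percentage is undefined for a risk group with ",
         "no cases", call. = FALSE)
  grp <- rownames(m)
  if (is.null(grp)) grp <- c("high", "low")
  data.frame(group = grp,
             transformed = as.integer(m[, 1L]),
             total = as.integer(totals),
             fraction = m[, 1L] / totals,
             percent = round(100 * m[, 1L] / totals, 1L),
             row.names = NULL)
}

#' Pearson chi-square test for an outcome-by-category table
#'
#' Uncorrected Pearson chi-square for a 2-row table with any number of
#' columns (e.g. transformation outcome against the three traditional
#' categories). The Yates continuity correction applies only to 2x2
#' tables (1 degree of freedom), so none is used here;
#' degrees of freedom are `(rows - 1)(cols - 1)`. Categories with no
#' observations contribute nothing and are dropped before testing, so an
#' empty category leaves the statistic unchanged.
#'
#' @param table 2 x k matrix (k >= 2) of non-negative integer counts
#'   with positive row totals and at least 2 non-empty columns.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
multi_group_chi_square <- function(table) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  if (nrow(m) != 2L || ncol(m) < 2L)
    stop("expected a 2 x k table with k >= 2", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m)))
    stop("table entries must be non-negative integers", call. = FALSE)
  m <- m[, colSums(m) > 0, drop = FALSE]  # empty-category invariance
  if (ncol(m) < 2L || any(rowSums(m) == 0))
    stop("degenerate table: need positive row totals and >= 2 non-empty ",
         "categories", call. = FALSE)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
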