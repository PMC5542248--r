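#' Construct a cytology case record
#'
#' A case record holds one subject's DNA-index (DI) measurements together
#' with the clinical group label and, optionally, follow-up information.
#' DI values are dimensionless ratios to the diploid reference: roughly 1
#' for diploid cells, 2 for tetraploid/G2 cells, and values of 2.3 or more
#' are conventionally called aneuploid.
#'
#' @param case_id single character string identifying the subject.
#' @param group one of `"normal"`, `"olk"`, `"oscc"`, `"unknown"`
#'   (case-insensitive). OLK is oral leukoplakia; OSCC is oral squamous
#'   cell carcinoma. Unknown-group cases may be scored but are never used
#'   for model training.
#' @param di_values numeric vector of finite, strictly positive DI values,
#'   one per measured cell.
#' @param followup_months optional non-negative number of months the
#'   subject was followed.
#' @param transformed optional logical: did the lesion undergo malignant
#'   transformation during follow-up? May only be set together with
#'   `followup_months`.
#'
#' @return An object of class `case_record`.
#' @examples
#' case_record("N01", "normal", c(0.98, 1.02, 1.97))
#' @export
case_record <- function(case_id, group, di_values,
                        followup_months = NULL, transformed = NULL) {
  if (!is.character(case_id) || length(case_id) != 1L || !nzchar(case_id))
    stop("'case_id' must be a single non-empty string", call. = FALSE)
  group <- match.arg(tolower(group), c("normal", "olk", "oscc", "unknown"))
  di_values <- as.numeric(di_values)
  if (length(di_values) > 0L && (any(!is.finite(di_values)) || any(di_values <= 0)))
    stop("all DI values must be finite and > 0 (case ", case_id, ")",
         call. = FALSE)
  if (!is.null(followup_months)) {
    followup_months <- as.numeric(followup_months)
    if (length(followup_months) != 1L || !is.finite(followup_months) ||
        followup_months < 0)
      stop("'followup_months' must be a single non-negative number",
           call. = FALSE)
  }
  if (!is.null(transformed)) {
    if (is.null(followup_months))
      stop("'transformed' may only be set when 'followup_months' is set",
           call. = FALSE)
    transformed <- as.logical(transformed)
    if (length(transformed) != 1L || is.na(transformed))
      stop("'transformed' must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(case_id = case_id, group = group, di_values = di_values,
         followup_months = followup_months, transformed = transformed),
    class = "case_record"
  )
}

#' @export
print.case_record <- function(x, ...) {
  cat("<case_record> ", x$case_id, " [", x$group, "]: ",
      length(x$di_values), " cells", sep = "")
  if (length(x$di_values) > 0L)
    cat(", DI range ", sprintf("%.2f-%.2f", min(x$di_values), max(x$di_values)),
        sep = "")
  if (!is.null(x$followup_months))
    cat("; follow-up ", x$followup_months, " mo",
        if (isTRUE(x$transformed)) " (transformed)" else "", sep = "")
  cat("\n")
  invisible(x)
}

# Map clinical group words to the single-character class factor used in
# feature tables: oscc -> "c", olk -> "k", normal -> "n", unknown -> "u".
group_to_label <- function(group) {
  unname(c(oscc = "c", olk = "k", normal = "n", unknown = "u")[group])
}

label_to_group <- function(label) {
  unname(c(c = "oscc", k = "olk", n = "normal", u = "unknown")[label])
}

#' Read cytology cases from a long-format CSV file
#'
#' The case file dialect is a long-format CSV with header
#' `case_id,group,di` and one measured cell per row; rows sharing a
#' `case_id` are aggregated, in file order, into one [case_record()].
#' Lines starting with `#` are treated as comments. An optional follow-up
#' CSV (`case_id,followup_months,transformed` with `transformed` coded
#' 0/1) attaches outcome data to matching cases.
#'
#' @param path path to the case CSV.
#' @param followup_path optional path to a follow-up CSV.
#' @return A list of [case_record()] objects, one per distinct `case_id`,
#'   in order of first appearance.
#' @seealso [write_cases()]
#' @export
read_cases <- function(path, followup_path = NULL) {
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                        check.names = FALSE)
  required <- c("case_id", "group", "di")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("case file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  di <- suppressWarnings(as.numeric(df$di))
  bad <- which(!is.finite(di) | di <= 0)
  if (length(bad) > 0L) {
    i <- bad[1L]
    stop("non-numeric or non-positive DI value '", df$di[i],
         "' at data row ", i, " of ", path, call. = FALSE)
  }
  grp <- tolower(df$group)
  allowed <- c("normal", "olk", "oscc", "unknown")
  badg <- which(!grp %in% allowed)
  if (length(badg) > 0L)
    stop("unknown group label '", df$group[badg[1L]], "' at data row ",
         badg[1L], " of ", path, "; allowed: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  ids <- unique(df$case_id)
  fu <- NULL
  if (!is.null(followup_path)) {
    if (!file.exists(followup_path))
      stop("follow-up file not found: ", followup_path, call. = FALSE)
    fu <- utils::read.csv(followup_path, comment.char = "#")
    need <- c("case_id", "followup_months", "transformed")
    if (!all(need %in% names(fu)))
      stop("follow-up file is missing required column(s): ",
           paste(setdiff(need, names(fu)), collapse = ", "), call. = FALSE)
  }
  lapply(ids, function(id) {
    rows <- df$case_id == id
    g <- unique(grp[rows])
    if (length(g) > 1L)
      stop("case ", id, " has conflicting group labels: ",
           paste(g, collapse = ", "), call. = FALSE)
    fm <- tr <- NULL
    if (!is.null(fu) && id %in% fu$case_id) {
      r <- fu[match(id, fu$case_id), ]
      fm <- as.numeric(r$followup_months)
      tr <- as.integer(r$transformed) == 1L
    }
    case_record(id, g, di[rows], followup_months = fm, transformed = tr)
  })
}

#' Write cytology cases to a long-format CSV file
#'
#' Inverse of [read_cases()]: one row per DI value, header
#' `case_id,group,di`.
#'
#' @param cases list of [case_record()] objects.
#' @param path output path.
#' @param followup_path optional path for a companion follow-up CSV;
#'   written only for cases carrying follow-up fields.
#' @return Invisibly, `path`.
#' @export
write_cases <- function(cases, path, followup_path = NULL) {
  stopifnot(is.list(cases), all(vapply(cases, inherits, logical(1), "case_record")))
  df <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(case_id = rep(cs$case_id, length(cs$di_values)),
               group = rep(cs$group, length(cs$di_values)),
               di = cs$di_values)
  }))
  if (is.null(df))
    df <- data.frame(case_id = character(), group = character(), di = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(followup_path)) {
    keep <- Filter(function(cs) !is.null(cs$followup_months), cases)
    fu <- do.call(rbind, lapply(keep, function(cs) {
      data.frame(case_id = cs$case_id,
                 followup_months = cs$followup_months,
                 transformed = as.integer(isTRUE(cs$transformed)))
    }))
    if (is.null(fu))
      fu <- data.frame(case_id = character(), followup_months = numeric(),
                       transformed = integer())
    utils::write.csv(fu, followup_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
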