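#' Density-estimation settings for the peaks transformation
#'
#' Controls the Gaussian kernel density estimate computed per case before
#' peak detection. The defaults reproduce `stats::density()`'s standard
#' behaviour: Silverman's rule-of-thumb bandwidth (`bw.nrd0`), 512 grid
#' points, and a grid extended 3 bandwidths past the data range.
#'
#' @param bandwidth either the string `"nrd0"` (Silverman rule,
#'   `h = 0.9 min(sd, IQR/1.349) n^(-1/5)`) or a fixed positive number in
#'   DI units.
#' @param grid_points number of equally spaced grid points (>= 8).
#' @param tail_extension grid extension beyond the data range, in
#'   bandwidth units (non-negative).
#' @return An object of class `density_config`.
#' @export
density_config <- function(bandwidth = "nrd0", grid_points = 512L,
                           tail_extension = 3) {
  if (is.character(bandwidth)) {
    bandwidth <- match.arg(bandwidth, "nrd0")
  } else {
    bandwidth <- as.numeric(bandwidth)
    if (length(bandwidth) != 1L || !is.finite(bandwidth) || bandwidth <= 0)
      stop("fixed 'bandwidth' must be a single positive number", call. = FALSE)
  }
  grid_points <- as.integer(grid_points)
  if (is.na(grid_points) || grid_points < 8L)
    stop("'grid_points' must be an integer >= 8", call. = FALSE)
  tail_extension <- as.numeric(tail_extension)
  if (!is.finite(tail_extension) || tail_extension < 0)
    stop("'tail_extension' must be non-negative", call. = FALSE)
  structure(list(kernel = "gaussian", bandwidth = bandwidth,
                 grid_points = grid_points, tail_extension = tail_extension),
            class = "density_config")
}

#' Estimate the DI density of one case
#'
#' Gaussian kernel density estimate of a case's DI values on an equally
#' spaced grid spanning `[min - cut*h, max + cut*h]` where `h` is the
#' bandwidth and `cut` the tail extension. This is the smooth curve whose
#' local maxima are the "peaks" of the peaks method.
#'
#' @param di_values numeric vector of at least 2 positive DI values with
#'   non-zero spread (when the Silverman rule is used).
#' @param config a [density_config()].
#' @return An object of class `density_curve` with fields `x` (grid, DI
#'   units), `y` (density) and `bw` (bandwidth used).
#' @export
estimate_density <- function(di_values, config = density_config()) {
  stopifnot(inherits(config, "density_config"))
  di_values <- as.numeric(di_values)
  if (length(di_values) < 2L)
    stop("density estimation needs at least 2 DI values, got ",
         length(di_values), call. = FALSE)
  if (any(!is.finite(di_values) | di_values <= 0))
    stop("DI values must be finite and > 0", call. = FALSE)
  if (identical(config$bandwidth, "nrd0") &&
      stats::sd(di_values) == 0 && stats::IQR(di_values) == 0)
    stop("degenerate sample: all DI values identical, the Silverman ",
         "bandwidth rule is undefined; supply a fixed bandwidth in ",
         "density_config()", call. = FALSE)
  bw <- if (identical(config$bandwidth, "nrd0"))
    stats::bw.nrd0(di_values) else config$bandwidth
  d <- stats::density(di_values, bw = bw, kernel = "gaussian",
                      n = config$grid_points, cut = config$tail_extension)
  structure(list(x = d$x, y = d$y, bw = d$bw), class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat("<density_curve> ", length(x$x), " grid points on [",
      sprintf("%.3f", min(x$x)), ", ", sprintf("%.3f", max(x$x)),
      "], bw = ", sprintf("%.4f", x$bw), "\n", sep = "")
  invisible(x)
}

#' Detect density peaks by first-derivative sign change
#'
#' Mimics the first derivative by the lagged differences of the density
#' values: a peak is a grid point where the curve stops rising and starts
#' falling (difference sign changes from positive to negative). The first
#' and last grid points are never peaks. A flat run (zero differences)
#' preceded by a rise and followed by a fall contributes exactly one peak,
#' located at the first grid point of the run.
#'
#' @param curve a `density_curve` from [estimate_density()], or any list
#'   with numeric fields `x` (strictly increasing) and `y`.
#' @return Sorted numeric vector of peak locations (DI units); empty when
#'   the curve has no interior local maximum.
#' @export
detect_peaks <- function(curve) {
  x <- as.numeric(curve$x); y <- as.numeric(curve$y)
  n <- length(x)
  stopifnot(n == length(y), n >= 2L, all(diff(x) > 0))
  s <- sign(diff(y))
  peaks <- numeric(0)
  rising <- FALSE        # have we seen a rise not yet resolved by a fall?
  candidate <- NA_real_  # first grid point of the current summit/plateau
  for (i in seq_along(s)) {
    if (s[i] > 0) {
      rising <- TRUE
      candidate <- x[i + 1L]
    } else if (s[i] < 0) {
      if (rising) peaks <- c(peaks, candidate)
      rising <- FALSE
    }
    # s[i] == 0: plateau, keep the candidate set at the end of the rise
  }
  peaks
}

#' Tally peak locations into the ten ploidy intervals
#'
#' Intervals are unit-width and centred on the natural ploidy numbers
#' 1..10: `[0.5, 1.5), [1.5, 2.5), ... [9.5, 10.5)`, with anything below
#' 0.5 folded into the first interval and anything at or above 9.5
#' (including values beyond 10.5) into the last. Interval k therefore
#' captures peaks of k-ploid cell populations. Boundaries are
#' lower-closed: a peak exactly at 1.5 counts in interval 2.
#'
#' @param locations numeric vector of peak locations (DI units).
#' @return Integer vector of length 10; its sum equals
#'   `length(locations)`.
#' @export
bin_peaks <- function(locations) {
  locations <- as.numeric(locations)
  stopifnot(all(is.finite(locations)))
  idx <- pmin(pmax(floor(locations + 0.5), 1), 10)
  counts <- tabulate(idx, nbins = 10L)
  storage.mode(counts) <- "integer"
  counts
}

#' Transform one case into its peaks feature row
#'
#' Runs the full per-case peaks transformation: density estimation of the
#' DI values, first-derivative peak detection, and interval tallying. The
#' clinical group is mapped to the class factor (oscc -> `c`, olk -> `k`,
#' normal -> `n`, unknown -> `u`).
#'
#' @param case a [case_record()] with at least 2 DI values.
#' @param config a [density_config()].
#' @return A one-row [feature_table()].
#' @export
transform_case <- function(case, config = density_config()) {
  stopifnot(inherits(case, "case_record"))
  curve <- tryCatch(estimate_density(case$di_values, config),
                    error = function(e)
                      stop("case ", case$case_id, ": ", conditionMessage(e),
                           call. = FALSE))
  counts <- bin_peaks(detect_peaks(curve))
  feature_table(matrix(counts, nrow = 1L), group_to_label(case$group),
                case$case_id)
}

#' Reconstruct a cohort dataset from case records
#'
#' Applies [transform_case()] to every case and stacks the rows, in input
#' order, into one feature table (the n-by-12 frame the classifiers
#' consume). If any case fails the transformation (for instance fewer
#' than 2 DI values), the whole reconstruction aborts with a report
#' naming every failing case; no partial table is returned.
#'
#' @param cases list of [case_record()] objects.
#' @param config a [density_config()].
#' @return A [feature_table()] with one row per case.
#' @export
reconstruct_dataset <- function(cases, config = density_config()) {
  stopifnot(is.list(cases))
  if (length(cases) == 0L)
    return(feature_table(matrix(integer(), ncol = 10L), character(), character()))
  rows <- lapply(cases, function(cs)
    tryCatch(transform_case(cs, config), error = function(e) e))
  failed <- vapply(rows, inherits, logical(1), "error")
  if (any(failed)) {
    msgs <- vapply(rows[failed], conditionMessage, character(1))
    stop("reconstruction failed for ", sum(failed), " case(s):\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  feature_table(out[paste0("V", 1:10)], out$label, out$case_id)
}
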