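#' Distributional profile of a simulated cytology group
#'
#' Each simulated case draws its cells' DI values from a Gaussian mixture.
#' The base mixture models the euploid populations (diploid cells near
#' DI 1 with a small tetraploid/G2 fraction near DI 2). With probability
#' `aneuploid_prevalence` a case is an aneuploid *carrier*: extra mixture
#' components are added at random locations over DI 2.5-8, modelling
#' clonal aneuploid populations, and the base weights are rescaled so all
#' weights still sum to 1. Carrier status is per case, not per cell.
#'
#' Default profiles:
#' \describe{
#'   \item{normal}{diploid (mean 1.0, sd 0.05, weight 0.93) +
#'     tetraploid (mean 2.0, sd 0.10, weight 0.07); never a carrier.}
#'   \item{olk_low}{normal base; carrier probability 0.1 with one
#'     aneuploid component of total weight 0.2.}
#'   \item{olk_high}{heavier tetraploid fraction (weights 0.7/0.3);
#'     carrier probability 0.6 with three aneuploid components of total
#'     weight 0.5.}
#'   \item{oscc}{as olk_high but every case is a carrier
#'     (prevalence 1), giving DI values spread across most ploidy
#'     intervals.}
#' }
#'
#' @param name one of `"normal"`, `"olk_low"`, `"olk_high"`, `"oscc"`.
#' @param components optional 3-column matrix (mean, sd, weight) of base
#'   mixture components; weights must sum to 1, means positive.
#' @param aneuploid_prevalence optional per-case carrier probability in
#'   `[0, 1]`.
#' @param cells_range integer pair: min and max cells per case (cell
#'   count drawn uniformly), default 50-300, a typical brush-biopsy
#'   yield.
#' @param aneuploid list describing the carrier components:
#'   `n_components`, `location_range` (DI interval the random component
#'   means are drawn from), `sd`, and `weight` (total mixture weight of
#'   all aneuploid components combined).
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(name = c("normal", "olk_low", "olk_high", "oscc"),
                          components = NULL, aneuploid_prevalence = NULL,
                          cells_range = c(50L, 300L), aneuploid = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    normal = list(
      components = rbind(c(1.0, 0.05, 0.93), c(2.0, 0.10, 0.07)),
      prevalence = 0,
      aneuploid = list(n_components = 0L, location_range = c(2.5, 8),
                       sd = 0.15, weight = 0)),
    olk_low = list(
      components = rbind(c(1.0, 0.05, 0.93), c(2.0, 0.10, 0.07)),
      prevalence = 0.1,
      aneuploid = list(n_components = 1L, location_range = c(2.5, 8),
                       sd = 0.15, weight = 0.2)),
    olk_high = list(
      components = rbind(c(1.0, 0.05, 0.70), c(2.0, 0.10, 0.30)),
      prevalence = 0.6,
      aneuploid = list(n_components = 3L, location_range = c(2.5, 8),
                       sd = 0.15, weight = 0.5)),
    oscc = list(
      components = rbind(c(1.0, 0.05, 0.70), c(2.0, 0.10, 0.30)),
      prevalence = 1,
      aneuploid = list(n_components = 3L, location_range = c(2.5, 8),
                       sd = 0.15, weight = 0.5)))
  if (is.null(components)) components <- defaults$components
  components <- as.matrix(components)
  if (ncol(components) != 3L)
    stop("'components' must have columns (mean, sd, weight)", call. = FALSE)
  colnames(components) <- c("mean", "sd", "weight")
  if (any(components[, "mean"] <= 0) || any(components[, "sd"] <= 0) ||
      any(components[, "weight"] < 0) ||
      abs(sum(components[, "weight"]) - 1) > 1e-8)
    stop("base component means/sds must be positive and weights sum to 1",
         call. = FALSE)
  if (is.null(aneuploid_prevalence)) aneuploid_prevalence <- defaults$prevalence
  if (!is.numeric(aneuploid_prevalence) || aneuploid_prevalence < 0 ||
      aneuploid_prevalence > 1)
    stop("'aneuploid_prevalence' must be in [0, 1]", call. = FALSE)
  if (is.null(aneuploid)) aneuploid <- defaults$aneuploid
  aneuploid <- utils::modifyList(defaults$aneuploid, aneuploid)
  cells_range <- as.integer(cells_range)
  if (length(cells_range) != 2L || any(cells_range < 1L) ||
      cells_range[1L] > cells_range[2L])
    stop("'cells_range' must be an increasing pair of positive integers",
         call. = FALSE)
  structure(list(name = name, components = components,
                 aneuploid_prevalence = aneuploid_prevalence,
                 cells_range = cells_range, aneuploid = aneuploid),
            class = "group_profile")
}

# clinical group label recorded on simulated cases
profile_group <- function(profile_name) {
  switch(profile_name, normal = "normal", olk_low = , olk_high = "olk",
         oscc = "oscc")
}

#' Simulate one cytology case
#'
#' Draws a cell count uniformly from the profile's range, realises
#' carrier status and the random aneuploid component locations for the
#' case, then draws each cell's DI from the resulting mixture. Draws that
#' would be non-positive are redrawn, truncating the mixture to DI > 0.
#' Uses (and advances) the current RNG state; seed control belongs to the
#' caller or to [simulate_cohort()].
#'
#' @param profile a [group_profile()].
#' @param case_id identifier for the new case.
#' @return A [case_record()].
#' @export
simulate_case <- function(profile, case_id = "sim1") {
  stopifnot(inherits(profile, "group_profile"))
  n_cells <- sample(profile$cells_range[1L]:profile$cells_range[2L], 1L)
  comp <- profile$components
  carrier <- stats::runif(1L) < profile$aneuploid_prevalence
  if (carrier && profile$aneuploid$n_components > 0L) {
    an <- profile$aneuploid
    locs <- stats::runif(an$n_components, an$location_range[1L],
                         an$location_range[2L])
    extra <- cbind(mean = locs, sd = rep(an$sd, an$n_components),
                   weight = rep(an$weight / an$n_components,
                                an$n_components))
    comp[, "weight"] <- comp[, "weight"] * (1 - an$weight)
    comp <- rbind(comp, extra)
  }
  assignment <- sample.int(nrow(comp), n_cells, replace = TRUE,
                           prob = comp[, "weight"])
  di <- stats::rnorm(n_cells, comp[assignment, "mean"], comp[assignment, "sd"])
  while (any(di <= 0)) {
    bad <- which(di <= 0)
    di[bad] <- stats::rnorm(length(bad), comp[assignment[bad], "mean"],
                            comp[assignment[bad], "sd"])
  }
  case_record(case_id, profile_group(profile$name), di)
}

#' Specify a synthetic cohort
#'
#' @param counts named integer vector of case counts per profile, names
#'   among `c("normal", "olk_low", "olk_high", "oscc")`.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param profiles optional named list of [group_profile()] overrides;
#'   defaults are used for any profile not listed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(counts, seed, profiles = NULL) {
  counts <- unlist(counts)
  allowed <- c("normal", "olk_low", "olk_high", "oscc")
  if (is.null(names(counts)) || !all(names(counts) %in% allowed))
    stop("'counts' must be named with profile names among: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  profs <- lapply(names(counts), function(nm) {
    if (!is.null(profiles) && nm %in% names(profiles)) {
      stopifnot(inherits(profiles[[nm]], "group_profile"))
      profiles[[nm]]
    } else group_profile(nm)
  })
  names(profs) <- names(counts)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 seed = as.integer(seed), profiles = profs),
            class = "cohort_spec")
}

#' Simulate a cytology cohort
#'
#' Generates the cases of every group in `spec`, deterministically given
#' `spec$seed`. Case ids are systematic: a group prefix (`N`, `KL`, `KH`,
#' `C`) plus a running index. Cases simulated from the two OLK profiles
#' both carry the clinical group label `"olk"`.
#'
#' @param spec a [cohort_spec()].
#' @return List of [case_record()] objects.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(c(normal = 3, oscc = 3), seed = 7))
#' length(cohort)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  prefixes <- c(normal = "N", olk_low = "KL", olk_high = "KH", oscc = "C")
  set.seed(spec$seed)
  out <- list()
  for (nm in names(spec$counts)) {
    n <- spec$counts[[nm]]
    if (n == 0L) next
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <-
        simulate_case(spec$profiles[[nm]],
                      sprintf("%s%03d", prefixes[[nm]], i))
    }
  }
  out
}
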