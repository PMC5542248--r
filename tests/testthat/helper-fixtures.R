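# Fixtures and independent oracles shared across test files.
# Everything is generated in code under fixed seeds; no data files.

# 90/10 diploid/tetraploid mixture: the canonical bimodal DI sample.
bimodal_sample <- function(n = 300L, seed = 42L) {
  set.seed(seed)
  n1 <- round(0.9 * n)
  c(stats::rnorm(n1, 1.0, 0.05), stats::rnorm(n - n1, 2.0, 0.1))
}

# Independent local-maximum oracle: scan every interior grid point; a
# maximal plateau (possibly of length 1) counts as one peak at its first
# point when the value before it is lower and the value after it is
# lower. Written as a direct scan, independent of detect_peaks' lagged-
# difference state machine.
brute_force_peaks <- function(x, y) {
  n <- length(y)
  peaks <- numeric(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L  # extend plateau
    if (y[i - 1L] < y[i] && j < n && y[j + 1L] < y[i])
      peaks <- c(peaks, x[i])
    i <- j + 1L
  }
  peaks
}

# Random piecewise-smooth curve on a random strictly increasing grid,
# with occasional exact plateaus planted by value rounding.
random_curve <- function(seed) {
  set.seed(seed)
  n <- sample(20:120, 1L)
  x <- sort(stats::runif(n, 0, 12))
  x <- x + seq_len(n) * 1e-9  # guard against duplicate grid points
  y <- abs(stats::rnorm(1)) * sin(stats::runif(1, 0.5, 3) * x) +
    cumsum(stats::rnorm(n, 0, 0.2))
  y <- y - min(y)
  if (stats::runif(1) < 0.5) y <- round(y, 1L)  # plant exact plateaus
  list(x = x, y = y)
}

# Small linearly separable feature table: class n peaks in intervals
# 1-2, class c adds peaks in intervals >= 5. The other columns carry
# deterministic class-independent variation so no column is constant.
separable_table <- function(n_per_class = 30L, prefix = "") {
  counts <- matrix(0L, 2L * n_per_class, 10L)
  lab <- character(2L * n_per_class)
  for (i in seq_len(n_per_class)) {
    counts[i, 1:2] <- c(1L + i %% 2L, 1L)
    lab[i] <- "n"
    j <- n_per_class + i
    counts[j, 1:2] <- c(1L, 1L)
    counts[j, 5L + i %% 4L] <- 1L
    lab[j] <- "c"
  }
  for (r in seq_len(2L * n_per_class)) {
    counts[r, 2L] <- 1L + (r %/% 4L) %% 2L
    counts[r, 3L] <- r %% 2L
    counts[r, 4L] <- (r %/% 2L) %% 2L
    counts[r, 9L] <- r %% 3L
    counts[r, 10L] <- (r + 1L) %% 3L
  }
  feature_table(counts, lab,
                paste0(prefix, lab, sprintf("%03d", seq_len(2L * n_per_class))))
}

# Three-case cohort with follow-up fields, for round-trip tests.
tiny_cohort <- function() {
  list(
    case_record("N01", "normal", c(0.95, 1.0, 1.05, 1.95),
                followup_months = 12, transformed = FALSE),
    case_record("K01", "olk", c(1.0, 1.1, 2.4, 3.7),
                followup_months = 30, transformed = TRUE),
    case_record("C01", "oscc", c(1.0, 2.5, 3.1, 4.8, 6.2)))
}

# A seeded synthetic two-cohort pair at n per class, feature space.
synthetic_cohort_pair <- function(n = 50L, seed_a = 101L, seed_b = 202L) {
  a <- simulate_cohort(cohort_spec(c(normal = n, oscc = n), seed = seed_a))
  b <- simulate_cohort(cohort_spec(c(normal = n, oscc = n), seed = seed_b))
  fa <- reconstruct_dataset(a)
  fb <- reconstruct_dataset(b)
  fb$case_id <- paste0("B", fb$case_id)
  list(a = fa, b = fb)
}
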