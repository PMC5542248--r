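#' @keywords internal
"_PACKAGE"

# FNV-1a hash over the serialized object; hex string used as a config
# digest in output provenance lines (no cryptographic claim).
config_digest <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); h stays a whole double
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    # multiply by the FNV prime 16777619 mod 2^32, exact via 16-bit split
    lo <- (h %% 65536) * 403
    hi <- (h %/% 65536) * 403 + (h %% 65536) * 256 + lo %/% 65536
    h <- (lo %% 65536) + (hi %% 65536) * 65536
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance_line <- function(seed, digest) {
  sprintf("# ocri2 %s seed=%s config=%s",
          as.character(utils::packageVersion("ocri2")),
          if (is.null(seed)) "NA" else seed, digest)
}

write_with_provenance <- function(writer, path, seed, digest) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  writer(tmp)
  lines <- readLines(tmp)
  writeLines(c(provenance_line(seed, digest), lines), path)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' A run configuration bundles everything one end-to-end run needs: the
#' seed, the density settings, the model spec, the risk cutoff, the
#' simulated cohort layout (optional) and the input/output paths. It can
#' also be loaded from a YAML file with sections `seed`, `density`,
#' `model`, `simulate` and `paths` via [read_run_config()].
#'
#' @param seed integer seed used by every stochastic stage.
#' @param density a [density_config()].
#' @param model a [model_spec()] (its seed is overridden by `seed`).
#' @param cutoff risk cutoff, default 0.5.
#' @param simulate optional named vector of cohort counts (see
#'   [cohort_spec()]); when present the pipeline starts by simulating.
#' @param paths named list of file paths: `cases` (input CSV when not
#'   simulating), and any of `cases_out`, `features_out`, `risk_out`,
#'   `traditional_out`, `report_out` to be written.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed, density = density_config(),
                       model = model_spec("rf"), cutoff = 0.5,
                       simulate = NULL, paths = list()) {
  stopifnot(inherits(density, "density_config"), inherits(model, "model_spec"))
  model$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), density = density, model = model,
                 cutoff = cutoff, simulate = simulate, paths = paths),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any of the sections `seed`, `density`
#'   (`bandwidth`, `grid_points`, `tail_extension`), `model` (`kind`,
#'   `cv_folds`, `cv_repeats`, `optimization_fraction`, `cutoff`),
#'   `simulate` (profile counts) and `paths`.
#' @param seed optional seed overriding the file's value.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(seed)) seed <- y$seed
  if (is.null(seed))
    stop("no seed: supply one in the config file or as an argument",
         call. = FALSE)
  dens <- do.call(density_config, y$density %||% list())
  margs <- y$model %||% list()
  cutoff <- margs$cutoff %||% 0.5
  margs$cutoff <- NULL
  if (!is.null(margs$kind)) {
    names(margs)[names(margs) == "kind"] <- "kind"
  }
  model <- do.call(model_spec, c(margs, list(seed = seed)))
  run_config(seed = seed, density = dens, model = model, cutoff = cutoff,
             simulate = if (!is.null(y$simulate)) unlist(y$simulate),
             paths = y$paths %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the cytology risk pipeline end to end
#'
#' Executes the stage chain simulate (or read) -> transform -> train ->
#' predict -> evaluate. Training uses only normal/OSCC rows; every row
#' (including OLK and unknown) is scored with an OCRI2 value and risk
#' class. Each written artifact starts with a provenance comment carrying
#' the package version, the seed and a digest of the configuration, so a
#' run can be reproduced exactly.
#'
#' @param config a [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @param dry_run if `TRUE`, validate the configuration and input paths
#'   and return without computing.
#' @return Invisibly, a list with the cohort, the feature table, the
#'   trained model, the risk assessment data frame, the traditional
#'   scores and the evaluation report.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  digest <- config_digest(unclass(config))
  if (is.null(config$simulate)) {
    if (is.null(config$paths$cases))
      stop("config must provide either a 'simulate' section or ",
           "paths$cases", call. = FALSE)
    if (!file.exists(config$paths$cases))
      stop("input case file not found: ", config$paths$cases, call. = FALSE)
  }
  if (dry_run) return(invisible(list(config = config, digest = digest)))

  cases <- if (!is.null(config$simulate)) {
    simulate_cohort(cohort_spec(config$simulate, seed = config$seed))
  } else {
    read_cases(config$paths$cases)
  }
  if (!is.null(config$paths$cases_out))
    write_with_provenance(function(p) write_cases(cases, p),
                          config$paths$cases_out, config$seed, digest)

  features <- reconstruct_dataset(cases, config$density)
  if (!is.null(config$paths$features_out))
    write_with_provenance(function(p) write_feature_table(features, p),
                          config$paths$features_out, config$seed, digest)

  traditional <- score_traditional(cases)
  if (!is.null(config$paths$traditional_out))
    write_with_provenance(
      function(p) utils::write.csv(traditional, p, row.names = FALSE,
                                   quote = FALSE),
      config$paths$traditional_out, config$seed, digest)

  model <- tune_and_train(training_rows(features), config$model)
  risk <- assess_risk(model, features, config$cutoff)
  if (!is.null(config$paths$risk_out))
    write_with_provenance(
      function(p) utils::write.csv(risk, p, row.names = FALSE, quote = FALSE),
      config$paths$risk_out, config$seed, digest)

  eval_rows <- features$label %in% c("c", "n")
  report <- NULL
  if (any(eval_rows)) {
    truth <- features$label[eval_rows]
    p <- risk$ocri2[eval_rows]
    pred <- ifelse(p >= config$cutoff, "c", "n")
    report <- confusion_and_metrics(truth, pred)
    if (length(unique(truth)) == 2L) report$auc <- auc_rank(p, truth)
    if (!is.null(config$paths$report_out)) {
      out <- list(provenance = list(version =
                    as.character(utils::packageVersion("ocri2")),
                    seed = config$seed, config = digest),
                  confusion = as.list(report$confusion),
                  sensitivity = report$sensitivity,
                  specificity = report$specificity,
                  ppv = report$ppv, npv = report$npv, auc = report$auc)
      jsonlite::write_json(out, config$paths$report_out, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
    }
  }
  invisible(list(cases = cases, features = features, model = model,
                 risk = risk, traditional = traditional, report = report,
                 digest = digest))
}
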