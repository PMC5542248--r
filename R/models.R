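#' Specify a risk classifier and its tuning protocol
#'
#' Describes one of the five supported classifiers together with the
#' tuning protocol used to optimise it: a hyperparameter grid searched by
#' repeated stratified k-fold cross-validation (default 10 folds, 5
#' repeats, i.e. 50 resample fits per candidate) on a random
#' stratified optimisation subset (default 70%) of the training cohort.
#' `svmfull` is the radial SVM trained on 100% of the cohort
#' (`optimization_fraction` forced to 1).
#'
#' Default grids: random forest (`rf`) and the alternative forest (`cf`,
#' a `ranger` probability forest) tune the features-per-split over
#' \{2, 6, 10\} with 500 trees; `svm`/`svmfull` tune cost over
#' \{0.25, 0.5, 1\} with a radial kernel; `knn` tunes k over \{5, 7, 9\}
#' on the untransformed counts.
#'
#' @param kind one of `"rf"`, `"svm"`, `"svmfull"`, `"knn"`, `"cf"`.
#' @param grid named list of hyperparameter candidate vectors; `NULL`
#'   selects the default grid for `kind`.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param cv_repeats number of cross-validation repeats.
#' @param optimization_fraction fraction of the training cohort used for
#'   tuning, in (0, 1]; ignored (forced to 1) for `svmfull`.
#' @param seed integer seed governing every random draw of the protocol.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("rf", "svm", "svmfull", "knn", "cf"),
                       grid = NULL, cv_folds = 10L, cv_repeats = 5L,
                       optimization_fraction = 0.7, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- switch(kind,
      rf = list(mtry = c(2L, 6L, 10L)),
      cf = list(mtry = c(2L, 6L, 10L)),
      svm = list(cost = c(0.25, 0.5, 1)),
      svmfull = list(cost = c(0.25, 0.5, 1)),
      knn = list(k = c(5L, 7L, 9L)))
  }
  if (!is.list(grid) || length(grid) == 0L || is.null(names(grid)))
    stop("'grid' must be a non-empty named list of candidate values",
         call. = FALSE)
  cv_folds <- as.integer(cv_folds)
  cv_repeats <- as.integer(cv_repeats)
  if (cv_folds < 2L) stop("'cv_folds' must be >= 2", call. = FALSE)
  if (cv_repeats < 1L) stop("'cv_repeats' must be >= 1", call. = FALSE)
  if (kind == "svmfull") optimization_fraction <- 1
  if (!is.numeric(optimization_fraction) || optimization_fraction <= 0 ||
      optimization_fraction > 1)
    stop("'optimization_fraction' must be in (0, 1]", call. = FALSE)
  structure(list(kind = kind, grid = grid, cv_folds = cv_folds,
                 cv_repeats = cv_repeats,
                 optimization_fraction = optimization_fraction,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Stratified optimisation/holdout split of a feature table
#'
#' Randomly splits a feature table into an optimisation part and a
#' holdout part, stratified by class label so each label's proportion is
#' preserved (per-class optimisation counts equal
#' `round(fraction * class size)`). Deterministic given `seed`.
#'
#' @param table a [feature_table()] containing at least 2 rows of each of
#'   the training classes `c` and `n`.
#' @param fraction fraction assigned to the optimisation part, in (0, 1];
#'   `fraction = 1` returns an empty holdout.
#' @param seed integer seed.
#' @return List with elements `optimization` and `holdout`, both
#'   [feature_table()]s; disjoint, union is the input.
#' @export
split_optimization_holdout <- function(table, fraction, seed) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  for (cls in c("c", "n"))
    if (sum(table$label == cls) < 2L)
      stop("stratified split needs >= 2 rows of class '", cls, "', got ",
           sum(table$label == cls), call. = FALSE)
  set.seed(as.integer(seed))
  opt_idx <- integer(0)
  for (cls in unique(table$label)) {
    idx <- which(table$label == cls)
    n_opt <- round(fraction * length(idx))
    opt_idx <- c(opt_idx, sort(sample(idx, n_opt)))
  }
  opt_idx <- sort(opt_idx)
  hold_idx <- setdiff(seq_len(nrow(table)), opt_idx)
  subset_ft <- function(i)
    feature_table(feature_counts(table)[i, , drop = FALSE],
                  table$label[i], table$case_id[i])
  list(optimization = subset_ft(opt_idx), holdout = subset_ft(hold_idx))
}

# Stratified fold assignment: every row gets a fold id 1..k, classes
# spread as evenly as possible across folds. Consumes the RNG stream.
assign_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# One model fit; x is the n x 10 integer count matrix, y a factor with
# levels c("c","n"). knn is a lazy learner, so its "fit" stores the data.
fit_backend <- function(kind, x, y, params) {
  switch(kind,
    rf = randomForest::randomForest(x = x, y = y, ntree = 500L,
                                    mtry = params$mtry),
    cf = ranger::ranger(x = x, y = y, probability = TRUE,
                        num.trees = 500L, mtry = params$mtry,
                        num.threads = 1L,
                        seed = sample.int(.Machine$integer.max, 1L)),
    svm = ,
    svmfull = e1071::svm(x = x, y = y, kernel = "radial",
                         cost = params$cost, probability = TRUE),
    knn = list(train = x, cl = y, k = params$k),
    stop("unknown model kind: ", kind, call. = FALSE))
}

# Class-c probability of each row of newx under a fitted backend.
prob_backend <- function(kind, fit, newx) {
  p <- switch(kind,
    rf = stats::predict(fit, newdata = newx, type = "prob")[, "c"],
    cf = stats::predict(fit, data = as.data.frame(newx),
                        num.threads = 1L)$predictions[, "c"],
    svm = ,
    svmfull = {
      pr <- stats::predict(fit, newdata = newx, probability = TRUE)
      attr(pr, "probabilities")[, "c"]
    },
    knn = {
      pred <- class::knn(train = fit$train, test = newx, cl = fit$cl,
                         k = fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "c", win, 1 - win)
    })
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' Tune and train a risk classifier
#'
#' Runs the full tuning protocol on a feature table containing only the
#' training classes (`c` = OSCC, `n` = normal): for every hyperparameter
#' candidate, mean classification accuracy is measured over
#' `cv_repeats x cv_folds` stratified resamples (identical fold
#' assignments for every candidate); the candidate with the highest mean
#' accuracy — ties broken toward the first candidate in grid order — is
#' refit on the whole table. All randomness is governed by `spec$seed`,
#' so repeated calls are identical.
#'
#' @param train_table a [feature_table()] whose labels are all `c` or
#'   `n`, with both classes present.
#' @param spec a [model_spec()].
#' @return An object of class `ocri2_model` carrying the fitted
#'   classifier, the selected hyperparameters, the tuning table (one row
#'   per candidate with its mean CV accuracy), the training class counts
#'   and the seed.
#' @export
tune_and_train <- function(train_table, spec) {
  stopifnot(inherits(train_table, "feature_table"), inherits(spec, "model_spec"))
  if (!all(train_table$label %in% c("c", "n")))
    stop("training table may only contain classes 'c' and 'n'; OLK and ",
         "unknown rows must be removed before training", call. = FALSE)
  y <- factor(train_table$label, levels = c("c", "n"))
  counts <- table(y)
  if (any(counts == 0L))
    stop("training requires both classes; got ", counts[["c"]], " 'c' and ",
         counts[["n"]], " 'n' rows", call. = FALSE)
  if (spec$cv_folds > min(counts))
    stop("cv_folds (", spec$cv_folds, ") exceeds the smallest class size (",
         min(counts), "); use cv_folds <= ", min(counts), call. = FALSE)
  x <- feature_counts(train_table)
  candidates <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)

  set.seed(spec$seed)
  folds <- replicate(spec$cv_repeats,
                     assign_folds(as.character(y), spec$cv_folds),
                     simplify = FALSE)
  acc <- numeric(nrow(candidates))
  for (ci in seq_len(nrow(candidates))) {
    params <- as.list(candidates[ci, , drop = FALSE])
    resample_acc <- numeric(0)
    for (r in seq_len(spec$cv_repeats)) {
      for (f in seq_len(spec$cv_folds)) {
        hold <- folds[[r]] == f
        fit <- fit_backend(spec$kind, x[!hold, , drop = FALSE], y[!hold],
                           params)
        p <- prob_backend(spec$kind, fit, x[hold, , drop = FALSE])
        pred <- ifelse(p >= 0.5, "c", "n")
        resample_acc <- c(resample_acc,
                          mean(pred == as.character(y[hold])))
      }
    }
    acc[ci] <- mean(resample_acc)
  }
  best <- which.max(acc)  # first candidate wins exact ties
  best_params <- as.list(candidates[best, , drop = FALSE])
  final_fit <- fit_backend(spec$kind, x, y, best_params)
  tuning <- cbind(candidates, mean_cv_accuracy = acc)
  structure(list(kind = spec$kind, fit = final_fit, params = best_params,
                 tuning = tuning,
                 class_counts = c(c = unname(counts[["c"]]),
                                  n = unname(counts[["n"]])),
                 spec = spec, seed = spec$seed),
            class = "ocri2_model")
}

#' @export
print.ocri2_model <- function(x, ...) {
  cat("<ocri2_model> kind =", x$kind, "| trained on", x$class_counts[["c"]],
      "OSCC +", x$class_counts[["n"]], "normal rows | seed", x$seed, "\n")
  cat("selected:", paste(names(x$params), unlist(x$params), sep = " = ",
                         collapse = ", "), "\n")
  print(x$tuning, row.names = FALSE)
  invisible(x)
}

#' Compute OCRI2, the cancer-risk probability, for feature rows
#'
#' OCRI2 is the model's predicted probability that a sample is OSCC, on
#' the scale 0 (no risk) to 1 (certain). For the forest models it is the
#' fraction of trees voting for the cancer class; for SVM and KNN it is
#' the model's class-c probability estimate (calibrated decision value
#' and neighbour vote fraction, respectively).
#'
#' @param model an [tune_and_train()] `ocri2_model`.
#' @param rows a [feature_table()] (any labels; labels are ignored).
#' @return Named numeric vector of OCRI2 values in `[0, 1]`, names taken
#'   from `case_id`.
#' @export
compute_ocri2 <- function(model, rows) {
  stopifnot(inherits(model, "ocri2_model"))
  if (is.null(model$fit)) stop("model has no fitted backend", call. = FALSE)
  stopifnot(inherits(rows, "feature_table"))
  p <- prob_backend(model$kind, model$fit, feature_counts(rows))
  stats::setNames(p, rows$case_id)
}

#' Stratify OCRI2 values into risk groups
#'
#' High risk is OCRI2 at or above the cutoff (boundary inclusive, default
#' 0.5); low risk is below it.
#'
#' @param ocri2 numeric vector of values in `[0, 1]`.
#' @param cutoff risk cutoff in `[0, 1]`, default 0.5.
#' @return Character vector in `c("high", "low")`.
#' @export
stratify_risk <- function(ocri2, cutoff = 0.5) {
  ocri2 <- as.numeric(ocri2)
  if (any(!is.finite(ocri2)) || any(ocri2 < 0) || any(ocri2 > 1))
    stop("OCRI2 values must lie in [0, 1]", call. = FALSE)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0, cutoff <= 1)
  ifelse(ocri2 >= cutoff, "high", "low")
}

#' Score a feature table and assign risk groups
#'
#' @param model an `ocri2_model`.
#' @param table a [feature_table()].
#' @param cutoff risk cutoff, default 0.5.
#' @return `data.frame` with columns `case_id`, `ocri2`, `risk_class`.
#' @export
assess_risk <- function(model, table, cutoff = 0.5) {
  p <- compute_ocri2(model, table)
  data.frame(case_id = table$case_id, ocri2 = unname(p),
             risk_class = stratify_risk(unname(p), cutoff))
}

#' Keep only the rows a classifier may be trained on
#'
#' Filters a feature table to the training classes `c` (OSCC) and `n`
#' (normal). OLK (`k`) and unknown (`u`) rows are the prediction
#' targets of the risk index and are never fitted on.
#'
#' @param table a [feature_table()].
#' @return A [feature_table()] containing only `c`/`n` rows.
#' @export
training_rows <- function(table) {
  keep <- table$label %in% c("c", "n")
  feature_table(feature_counts(table)[keep, , drop = FALSE],
                table$label[keep], table$case_id[keep])
}

#' Two-cohort cross-examination
#'
#' Runs the cross-cohort validation protocol in both directions: the
#' model is tuned and trained on the normal/OSCC rows of one cohort
#' (using `spec`'s optimisation fraction and CV protocol) and evaluated
#' on all normal/OSCC rows of the other cohort; then the roles are
#' reversed. OLK and unknown rows are never used for fitting. The same
#' spec and seed are used for both directions.
#'
#' @param set_a,set_b [feature_table()]s, each containing both `c` and
#'   `n` rows.
#' @param spec a [model_spec()].
#' @param cutoff risk cutoff for class prediction, default 0.5.
#' @return List of class `cross_examination` with elements `a_to_b` and
#'   `b_to_a` (each an `evaluation_report`, see
#'   [confusion_and_metrics()]) and `models` (the two fitted models).
#' @export
cross_examine <- function(set_a, set_b, spec, cutoff = 0.5) {
  stopifnot(inherits(set_a, "feature_table"), inherits(set_b, "feature_table"),
            inherits(spec, "model_spec"))
  one_direction <- function(train_tab, test_tab) {
    tr <- training_rows(train_tab)
    split <- split_optimization_holdout(tr, spec$optimization_fraction,
                                        spec$seed)
    model <- tune_and_train(split$optimization, spec)
    te <- training_rows(test_tab)
    p <- unname(compute_ocri2(model, te))
    pred <- ifelse(stratify_risk(p, cutoff) == "high", "c", "n")
    report <- confusion_and_metrics(te$label, pred)
    report$auc <- auc_rank(p, te$label)
    list(model = model, report = report)
  }
  fwd <- one_direction(set_a, set_b)
  rev <- one_direction(set_b, set_a)
  structure(list(a_to_b = fwd$report, b_to_a = rev$report,
                 models = list(a = fwd$model, b = rev$model)),
            class = "cross_examination")
}

#' @export
print.cross_examination <- function(x, ...) {
  cat("<cross_examination>\n-- train A, test B --\n")
  print(x$a_to_b)
  cat("-- train B, test A --\n")
  print(x$b_to_a)
  invisible(x)
}
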