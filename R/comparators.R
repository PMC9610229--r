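# Machine-learning comparators (support-vector and random-forest
# regressors on log10(Dk)) and the evaluation metrics used to compare all
# three models: MSE, adjusted R^2, and log-fold coverage bands.

.comparator_design <- function(table, transforms = NULL) {
  table <- normalize_qspr_table(table)
  if (!"log10_dk" %in% names(table)) {
    if (!"dk" %in% names(table))
      stop("input error: table needs a dk or log10_dk column", call. = FALSE)
    table$log10_dk <- log10(table$dk)
  }
  y <- table$log10_dk
  if (is.null(transforms)) {
    transforms <- list()
    for (pr in QSPR_PREDICTORS) {
      x <- table[[pr]]
      tr <- select_transform(x, y)
      transforms[[pr]] <- if (tr == "exponential")
        .new_transform_spec(tr, center = mean(x), scale = stats::sd(x))
      else .new_transform_spec(tr)
    }
  } else {
    transforms <- .as_transform_specs(transforms)
    for (pr in names(transforms)) {
      s <- transforms[[pr]]
      if (s$transform == "exponential" && is.na(s$center))
        transforms[[pr]] <- .new_transform_spec("exponential",
                                                center = mean(table[[pr]]),
                                                scale = stats::sd(table[[pr]]))
    }
  }
  X <- sapply(names(transforms), function(pr)
    .apply_spec(table[[pr]], transforms[[pr]]))
  list(x = as.matrix(X), y = y, transforms = transforms)
}

.predict_design <- function(predictor, newdata) {
  newdata <- normalize_qspr_table(newdata)
  X <- sapply(names(predictor$transforms), function(pr)
    .apply_spec(newdata[[pr]], predictor$transforms[[pr]]))
  matrix(X, nrow = nrow(newdata),
         dimnames = list(NULL, names(predictor$transforms)))
}

#' Support-vector comparator for log10(Dk)
#'
#' Epsilon-regression SVM on the same transformed design matrix as the
#' linear workflow (the transform spec can be taken from a fitted
#' [fit_qspr()] model so all models see identical predictors; by default it
#' is re-derived with [select_transform()]). Inputs are standardized inside
#' the SVM. The radial-basis kernel and default regularization are used
#' unless overridden — no kernel or hyperparameters are prescribed by the
#' workflow, so they are surfaced here rather than hidden.
#'
#' @param table Training rows (same schema as [fit_qspr()]).
#' @param transforms Optional transform spec or `"qspr_model"` to reuse.
#' @param kernel,cost,epsilon,gamma Hyperparameters passed to
#'   [e1071::svm()]; `gamma = NULL` keeps that function's default.
#' @param seed Integer seed; fitting is deterministic given seed and data.
#' @return A `"dk_predictor"` object; use [predict_comparator()] on new rows.
#' @export
fit_svm <- function(table, transforms = NULL, kernel = "radial", cost = 1,
                    epsilon = 0.1, gamma = NULL, seed = 1L) {
  d <- .comparator_design(table, transforms)
  if (nrow(d$x) < 3L)
    stop("insufficient data: need at least 3 training rows", call. = FALSE)
  set.seed(seed)
  args <- list(x = d$x, y = d$y, type = "eps-regression", kernel = kernel,
               cost = cost, epsilon = epsilon, scale = TRUE)
  if (!is.null(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  structure(list(fit = fit, transforms = d$transforms, type = "svm",
                 seed = seed, y_range = range(d$y)),
            class = "dk_predictor")
}

#' Random-forest comparator for log10(Dk)
#'
#' Seeded [randomForest::randomForest()] regressor on the shared
#' transformed design. Defaults to 500 trees with the standard regression
#' feature subsampling (p/3); all hyperparameters are surfaced.
#'
#' @inheritParams fit_svm
#' @param ntree Number of trees (default 500).
#' @param ... Further arguments to [randomForest::randomForest()]
#'   (e.g. `mtry`, `nodesize`, `maxnodes`, `replace`, `sampsize`).
#' @return A `"dk_predictor"` object with out-of-bag MSE in `$oob_mse`.
#' @export
fit_rf <- function(table, transforms = NULL, ntree = 500, seed = 1L, ...) {
  d <- .comparator_design(table, transforms)
  if (nrow(d$x) < 2L)
    stop("insufficient data: need at least 2 training rows", call. = FALSE)
  set.seed(seed)
  fit <- randomForest::randomForest(x = d$x, y = d$y, ntree = ntree, ...)
  structure(list(fit = fit, transforms = d$transforms, type = "rf",
                 seed = seed, y_range = range(d$y),
                 oob_mse = unname(fit$mse[length(fit$mse)])),
            class = "dk_predictor")
}

#' Predict log10(Dk) with a fitted comparator
#'
#' @param predictor A `"dk_predictor"` from [fit_svm()] or [fit_rf()].
#' @param newdata Data frame of drug-property rows (same schema as the
#'   training table; the `dk` column is not required).
#' @return Numeric vector of predicted log10(Dk).
#' @export
predict_comparator <- function(predictor, newdata) {
  stopifnot(inherits(predictor, "dk_predictor"))
  X <- .predict_design(predictor, newdata)
  unname(stats::predict(predictor$fit, X))
}

#' @export
predict.dk_predictor <- function(object, newdata, ...) {
  predict_comparator(object, newdata)
}

#' @export
print.dk_predictor <- function(x, ...) {
  cat(sprintf("%s comparator for log10(Dk) (seed %d)\n",
              switch(x$type, svm = "Support-vector", rf = "Random-forest"),
              x$seed))
  invisible(x)
}

#' Prediction-quality metrics on the log10(Dk) scale
#'
#' Mean squared error of predicted versus observed log10(Dk), the fractions
#' of predictions within 0.5 and 1 log10 units of the observations (the
#' coverage bands drawn on predicted-vs-observed plots; 0.5 log spans about
#' a 1/3x-3x fold range), and optionally adjusted R^2 when the number of
#' model degrees of freedom (predictors) is supplied.
#'
#' @param predicted,observed Equal-length numeric vectors of log10(Dk).
#' @param model_df Number of model predictors, for adjusted R^2; `NULL`
#'   (default) omits it.
#' @return An `"eval_report"`: list with `mse`, `adjusted_r2`,
#'   `frac_within_half_log`, `frac_within_one_log`, `n`.
#' @export
evaluate <- function(predicted, observed, model_df = NULL) {
  if (length(predicted) != length(observed))
    stop("input error: predicted and observed must have equal length",
         call. = FALSE)
  n <- length(observed)
  if (n < 1L) stop("input error: need at least one pair", call. = FALSE)
  err <- predicted - observed
  adj <- NA_real_
  if (!is.null(model_df)) {
    ss_res <- sum(err^2)
    ss_tot <- sum((observed - mean(observed))^2)
    r2 <- 1 - ss_res / ss_tot
    adj <- 1 - (1 - r2) * (n - 1) / (n - model_df - 1)
  }
  structure(
    list(mse = mean(err^2),
         adjusted_r2 = adj,
         frac_within_half_log = mean(abs(err) <= 0.5),
         frac_within_one_log = mean(abs(err) <= 1),
         n = n),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(format_eval_report(x), "\n")
  invisible(x)
}

#' One-line summary of an evaluation report
#' @param report An `"eval_report"`.
#' @return A character scalar.
#' @export
format_eval_report <- function(report) {
  sprintf("n=%d MSE=%.4g%s within0.5log=%.1f%% within1log=%.1f%%",
          report$n, report$mse,
          if (is.na(report$adjusted_r2)) ""
          else sprintf(" adjR2=%.3f", report$adjusted_r2),
          100 * report$frac_within_half_log,
          100 * report$frac_within_one_log)
}

#' Write an evaluation report as JSON
#' @param report An `"eval_report"`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
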