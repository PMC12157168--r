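#' Root-mean-square error
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return \eqn{\sqrt{\sum_i (y_i - \hat y_i)^2 / n}}.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 1L) {
    stop_formbo("y and yhat must have equal positive length", "formbo_config_error")
  }
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2}: the
#' goodness-of-fit between predictions and observations. Can be negative
#' for a predictor worse than the observed mean.
#'
#' @inheritParams rmse
#' @return \eqn{R^2 \le 1}.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L) {
    stop_formbo("need at least 2 paired values", "formbo_config_error")
  }
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop_formbo("R^2 undefined for constant observations", "formbo_metric_error")
  1 - sum((y - yhat)^2) / sstot
}

#' k-fold cross-validation of a surrogate specification
#'
#' Rows are shuffled once with the seed and cut into `k` contiguous folds.
#' The fold RMSEs yield `rmse_mean` and `rmse_sd` (population standard
#' deviation across folds, the "±" of a screening report); \eqn{R^2} is
#' computed once on the pooled out-of-fold predictions, which is stabler
#' than averaging per-fold values on small folds. Deterministic given the
#' seed and a deterministic model.
#'
#' @param spec A surrogate specification accepted by [fit_model()].
#' @param dataset A [formulation_dataset()].
#' @param features Optional feature subset to train on.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed (shuffle and per-fold fits).
#' @return An object of class `eval_metrics`: `rmse_mean`, `rmse_sd`, `r2`,
#'   `k`, `seed`, per-fold RMSEs and pooled out-of-fold predictions.
#' @export
kfold_cv <- function(spec, dataset, features = NULL, k = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "formulation_dataset"))
  n <- n_observations(dataset)
  if (k < 2L || k > n) stop_formbo("need 2 <= k <= n folds", "formbo_config_error")
  features <- features %||% feature_names(dataset$space)
  X <- as.data.frame(dataset_features(dataset, features))
  y <- dataset_response(dataset)
  perm <- with_local_seed(derive_seed(seed, 3L), sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of <- rep(seq_len(k), times = sizes)
  oof <- numeric(n)
  fold_rmse <- numeric(k)
  for (f in seq_len(k)) {
    test_idx <- perm[fold_of == f]
    train_idx <- setdiff(perm, test_idx)
    fit <- fit_model(spec, X[train_idx, , drop = FALSE], y[train_idx],
                     seed = derive_seed(seed, 100L + f))
    pred <- predict(fit, X[test_idx, , drop = FALSE])
    oof[test_idx] <- pred
    fold_rmse[f] <- rmse(y[test_idx], pred)
  }
  structure(
    list(rmse_mean = mean(fold_rmse),
         rmse_sd = sqrt(mean((fold_rmse - mean(fold_rmse))^2)),
         r2 = r_squared(y, oof),
         k = as.integer(k), seed = as.integer(seed),
         fold_rmse = fold_rmse, oof_predictions = oof),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("RMSE = %.3g +/- %.2g, R^2 = %.3g (%d-fold CV)\n",
              x$rmse_mean, x$rmse_sd, x$r2, x$k))
  invisible(x)
}

#' Holdout prediction accuracy
#'
#' Scores a fitted model on a test set that must be disjoint from all
#' training and selection data (the caller's responsibility). A prediction
#' is counted correct when its absolute error is within `tolerance`
#' response units; there is no universal tolerance — a sensible choice is
#' the assay's own variability.
#'
#' @param model A `fitted_model`.
#' @param test A [formulation_dataset()] of held-out observations.
#' @param tolerance Positive correctness tolerance (response units).
#' @return An object of class `holdout_report`: `n_correct`, `n_total`,
#'   `accuracy` (exactly `n_correct / n_total`), `tolerance` and a
#'   `per_row` data frame (observed, predicted, abs_error, correct).
#' @export
holdout_accuracy <- function(model, test, tolerance) {
  stopifnot(inherits(model, "fitted_model"), inherits(test, "formulation_dataset"))
  if (!is_number(tolerance) && !identical(tolerance, Inf)) {
    stop_formbo("tolerance must be a positive number", "formbo_config_error")
  }
  if (tolerance <= 0) stop_formbo("tolerance must be > 0", "formbo_config_error")
  if (n_observations(test) < 1L) stop_formbo("empty test set", "formbo_config_error")
  obs <- dataset_response(test)
  pred <- predict(model, dataset_features(test, model$feature_names))
  err <- abs(pred - obs)
  correct <- err <= tolerance
  structure(
    list(n_correct = sum(correct), n_total = length(obs),
         accuracy = sum(correct) / length(obs), tolerance = tolerance,
         per_row = data.frame(observed = obs, predicted = pred,
                              abs_error = err, correct = correct)),
    class = "holdout_report"
  )
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf("Holdout accuracy: %.1f%% (%d/%d correct within +/- %g)\n",
              100 * x$accuracy, x$n_correct, x$n_total, x$tolerance))
  invisible(x)
}

#' Prediction-error table
#'
#' Per-row signed errors (`delta = predicted - observed`) with summary
#' statistics, as reported in model-validation tables of formulation
#' studies.
#'
#' @param observed,predicted Paired numeric vectors (at least one row).
#' @return An object of class `prediction_error_table` with `rows`
#'   (observed, predicted, delta, abs_error) and `summary` (mean signed
#'   delta, mean absolute error, max absolute error).
#' @export
prediction_error_summary <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L) {
    stop_formbo("observed and predicted must have equal positive length",
                "formbo_config_error")
  }
  delta <- predicted - observed
  structure(
    list(rows = data.frame(observed = observed, predicted = predicted,
                           delta = delta, abs_error = abs(delta)),
         summary = list(mean_delta = mean(delta),
                        mean_abs_error = mean(abs(delta)),
                        max_abs_error = max(abs(delta)))),
    class = "prediction_error_table"
  )
}

#' @export
print.prediction_error_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Prediction errors over %d rows: mean delta = %.3g, mean |delta| = %.3g, max |delta| = %.3g\n",
              nrow(x$rows), s$mean_delta, s$mean_abs_error, s$max_abs_error))
  invisible(x)
}

#' Write a prediction-error table as CSV
#'
#' @param table A `prediction_error_table`.
#' @param path Output path (columns observed, predicted, delta).
#' @export
write_prediction_errors <- function(table, path) {
  stopifnot(inherits(table, "prediction_error_table"))
  utils::write.csv(table$rows[, c("observed", "predicted", "delta")], path,
                   row.names = FALSE)
  invisible(path)
}
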