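#' Tree-ensemble surrogate specification
#'
#' Two tree-ensemble families are supported, both with fixed screening-scale
#' hyperparameters (no tuning):
#' * `"randomized_split_ensemble"` — extremely randomized trees: every tree
#'   is grown on the full sample (no bootstrap), all features are split
#'   candidates, and one uniformly random threshold per candidate feature is
#'   drawn at each split, the best by variance reduction being kept.
#'   Prediction is the arithmetic mean over trees. Defaults: 30 trees,
#'   maximum depth 20.
#' * `"gradient_boosted"` — stagewise depth-limited regression trees fit to
#'   residuals with shrinkage and an L2 leaf penalty; prediction is the
#'   additive sum. Defaults: depth 3, 100 rounds, learning rate 0.1,
#'   lambda 1.
#'
#' All randomness is consumed at fit time through the seed; refitting with
#' the same seed reproduces predictions bit-identically, and training rows
#' are canonicalized (sorted) before fitting so results do not depend on
#' row order.
#'
#' @param mode `"randomized_split_ensemble"` or `"gradient_boosted"`.
#' @param n_estimators Trees in the randomized ensemble.
#' @param max_depth Maximum tree depth (`20` randomized, `3` boosted by
#'   default).
#' @param min_samples_split Minimum node size to attempt a split
#'   (randomized mode).
#' @param learning_rate,boosting_rounds,reg_lambda Boosted-mode settings.
#'   `boosting_rounds = 0` yields the training-mean predictor.
#' @return An object of class `c("tree_ensemble_spec", "surrogate_spec")`.
#' @export
tree_ensemble_spec <- function(mode = c("randomized_split_ensemble", "gradient_boosted"),
                               n_estimators = 30L, max_depth = NULL,
                               min_samples_split = 2L,
                               learning_rate = 0.1, boosting_rounds = 100L,
                               reg_lambda = 1) {
  mode <- match.arg(mode)
  max_depth <- max_depth %||% if (mode == "randomized_split_ensemble") 20L else 3L
  if (n_estimators <= 0 || max_depth <= 0) {
    stop_formbo("n_estimators and max_depth must be positive", "formbo_config_error")
  }
  if (boosting_rounds < 0 || learning_rate <= 0) {
    stop_formbo("invalid boosting settings", "formbo_config_error")
  }
  structure(list(mode = mode, n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 learning_rate = learning_rate,
                 boosting_rounds = as.integer(boosting_rounds),
                 reg_lambda = reg_lambda),
            class = c("tree_ensemble_spec", "surrogate_spec"))
}

#' Ordinary-least-squares surrogate specification
#'
#' @param intercept Include an intercept (default `TRUE`). No
#'   regularization.
#' @return An object of class `c("linear_model_spec", "surrogate_spec")`.
#' @export
linear_model_spec <- function(intercept = TRUE) {
  structure(list(intercept = isTRUE(intercept)),
            class = c("linear_model_spec", "surrogate_spec"))
}

#' Oracle surrogate specification (known response function)
#'
#' Wraps a fixed function of the features as a "model" that ignores the
#' training data. Useful for testing evaluation machinery against a perfect
#' or otherwise known predictor.
#'
#' @param fun Function mapping a feature matrix/data frame to predictions.
#' @return An object of class `c("oracle_model_spec", "surrogate_spec")`.
#' @export
oracle_model_spec <- function(fun) {
  stopifnot(is.function(fun))
  structure(list(fun = fun), class = c("oracle_model_spec", "surrogate_spec"))
}

# Complexity order used for model-selection tie-breaks:
# linear < randomized ensemble < boosted.
spec_complexity <- function(spec) {
  if (inherits(spec, "linear_model_spec")) return(1)
  if (inherits(spec, "oracle_model_spec")) return(0)
  if (identical(spec$mode, "randomized_split_ensemble")) return(2)
  3
}

spec_label <- function(spec) {
  if (inherits(spec, "linear_model_spec")) return("linear")
  if (inherits(spec, "oracle_model_spec")) return("oracle")
  if (inherits(spec, "gp_spec")) return("gaussian_process")
  if (identical(spec$mode, "randomized_split_ensemble")) return("randomized_split_ensemble")
  "gradient_boosted"
}

spec_hyperparameters <- function(spec) {
  if (inherits(spec, "linear_model_spec")) return(list(intercept = spec$intercept))
  if (inherits(spec, "oracle_model_spec")) return(list())
  if (identical(spec$mode, "randomized_split_ensemble")) {
    return(list(n_estimators = spec$n_estimators, max_depth = spec$max_depth))
  }
  list(max_depth = spec$max_depth, boosting_rounds = spec$boosting_rounds,
       learning_rate = spec$learning_rate, reg_lambda = spec$reg_lambda)
}

# Canonical row order: lexicographic by feature columns then response, so
# fitted models are invariant to the order training rows arrive in.
canonical_order <- function(X, y) {
  do.call(order, c(unname(as.data.frame(X)), list(y)))
}

#' Fit a surrogate model
#'
#' @param spec A surrogate specification ([tree_ensemble_spec()],
#'   [linear_model_spec()], [oracle_model_spec()]).
#' @param X Feature matrix or data frame (original units; columns named).
#' @param y Response vector.
#' @param seed Integer seed consumed at fit time.
#' @return An object of class `fitted_model` with a [predict()] method
#'   mapping a feature matrix/data frame to predictions.
#' @export
fit_model <- function(spec, X, y, seed = 1L) {
  UseMethod("fit_model")
}

#' @export
fit_model.tree_ensemble_spec <- function(spec, X, y, seed = 1L) {
  X <- as.data.frame(X)
  if (nrow(X) < 2L) stop_formbo("need at least 2 training rows", "formbo_config_error")
  ord <- canonical_order(X, y)
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  feature_names <- names(X)
  if (spec$mode == "randomized_split_ensemble") {
    df <- X; df$.response <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".response", data = df,
      num.trees = spec$n_estimators, max.depth = spec$max_depth,
      mtry = length(feature_names), replace = FALSE, sample.fraction = 1,
      splitrule = "extratrees", num.random.splits = 1L,
      min.node.size = spec$min_samples_split,
      seed = derive_seed(seed, 11L), num.threads = 1L
    )
    kind <- "ranger"
  } else if (spec$boosting_rounds == 0L) {
    fit <- list(mean = mean(y))
    kind <- "mean"
  } else {
    dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
    fit <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = spec$max_depth,
                    eta = spec$learning_rate, lambda = spec$reg_lambda,
                    base_score = mean(y), nthread = 1L,
                    seed = derive_seed(seed, 13L)),
      data = dm, nrounds = spec$boosting_rounds, verbose = 0
    )
    kind <- "xgboost"
  }
  new_fitted_model(spec, feature_names, kind, fit, seed)
}

#' @export
fit_model.linear_model_spec <- function(spec, X, y, seed = 1L) {
  X <- as.data.frame(X)
  M <- as.matrix(X)
  A <- if (spec$intercept) cbind(`(Intercept)` = 1, M) else M
  coefs <- qr.coef(qr(A), y)
  coefs[is.na(coefs)] <- 0
  new_fitted_model(spec, names(X), "linear", list(coefficients = coefs), seed)
}

#' @export
fit_model.oracle_model_spec <- function(spec, X, y, seed = 1L) {
  new_fitted_model(spec, colnames(as.data.frame(X)), "oracle", list(fun = spec$fun), seed)
}

new_fitted_model <- function(spec, feature_names, kind, fit, seed) {
  structure(list(spec = spec, feature_names = feature_names, kind = kind,
                 fit = fit, seed = seed),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s on %d feature(s)\n",
              spec_label(x$spec), length(x$feature_names)))
  invisible(x)
}

#' @export
predict.fitted_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  miss <- setdiff(object$feature_names, names(df))
  if (length(miss)) {
    stop_formbo(paste0("missing feature(s): ", paste(miss, collapse = ", ")),
                "formbo_schema_error")
  }
  M <- as.matrix(df[, object$feature_names, drop = FALSE])
  switch(object$kind,
    ranger = ranger::predictions(stats::predict(object$fit, data = as.data.frame(M),
                                                num.threads = 1L)),
    xgboost = stats::predict(object$fit, xgboost::xgb.DMatrix(M)),
    mean = rep(object$fit$mean, nrow(M)),
    linear = {
      A <- if (object$spec$intercept) cbind(1, M) else M
      drop(A %*% object$fit$coefficients)
    },
    oracle = as.numeric(object$fit$fun(df[, object$feature_names, drop = FALSE])),
    forest_tables = predict_forest_tables(object$fit, M),
    stop_formbo("unknown model kind", "formbo_config_error")
  )
}

#' Per-tree predictions of a randomized ensemble
#'
#' @param model A `fitted_model` in randomized-split-ensemble mode.
#' @param newdata Feature matrix/data frame.
#' @return Matrix (rows = observations, columns = trees).
#' @export
predict_per_tree <- function(model, newdata) {
  stopifnot(inherits(model, "fitted_model"), identical(model$kind, "ranger"))
  df <- as.data.frame(newdata)[, model$feature_names, drop = FALSE]
  stats::predict(model$fit, data = df, predict.all = TRUE, num.threads = 1L)$predictions
}

#' Cross-validated model selection
#'
#' Runs identical k-fold cross-validation (same seed, hence the same folds)
#' for every candidate specification and returns the one with the lowest
#' mean CV RMSE. Ties within `tie_tol` break toward lower model complexity
#' (linear, then randomized ensemble, then boosted), then input order.
#'
#' @param candidates List of surrogate specifications.
#' @param dataset A [formulation_dataset()].
#' @param features Optional feature subset.
#' @param k Number of folds.
#' @param seed Integer seed (folds and fits).
#' @param tie_tol Absolute RMSE difference treated as a tie.
#' @return List with `best` (spec), `best_index`, and `metrics` (data frame
#'   of per-candidate CV results).
#' @export
select_model <- function(candidates, dataset, features = NULL, k = 5L, seed = 1L,
                         tie_tol = 1e-9) {
  stopifnot(length(candidates) >= 1L)
  rows <- lapply(seq_along(candidates), function(i) {
    m <- tryCatch(kfold_cv(candidates[[i]], dataset, features = features,
                           k = k, seed = seed),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    data.frame(model = spec_label(candidates[[i]]), rmse_mean = m$rmse_mean,
               rmse_sd = m$rmse_sd, r2 = m$r2,
               complexity = spec_complexity(candidates[[i]]), index = i)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop_formbo("cross-validation failed for every candidate",
                                 "formbo_numeric_error")
  tab <- do.call(rbind, rows)
  best_rmse <- min(tab$rmse_mean)
  tied <- tab[tab$rmse_mean <= best_rmse + tie_tol, ]
  tied <- tied[order(tied$complexity, tied$index), ]
  best_index <- tied$index[1L]
  list(best = candidates[[best_index]], best_index = best_index,
       metrics = tab[, c("model", "rmse_mean", "rmse_sd", "r2")])
}

#' Save or load a fitted surrogate as JSON
#'
#' Tree structures are serialized explicitly (randomized ensembles as node
#' tables, boosted models as the booster's JSON) so fitted models are
#' portable across sessions; predictions from a reloaded model match the
#' original.
#'
#' @param model A `fitted_model`.
#' @param path File path.
#' @return `load_model()` returns a `fitted_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  payload <- list(
    kind = model$kind,
    feature_names = model$feature_names,
    spec = unclass(model$spec)[setdiff(names(unclass(model$spec)), "fun")],
    spec_class = class(model$spec)
  )
  if (model$kind == "ranger") {
    payload$trees <- lapply(seq_len(model$fit$num.trees), function(i) {
      ti <- ranger::treeInfo(model$fit, i)
      list(left = ti$leftChild, right = ti$rightChild,
           splitvar = ti$splitvarID, splitval = ti$splitval,
           terminal = ti$terminal, prediction = ti$prediction)
    })
  } else if (model$kind == "xgboost") {
    payload$booster_json <- rawToChar(xgboost::xgb.save.raw(model$fit, raw_format = "json"))
  } else if (model$kind == "linear") {
    payload$coefficients <- as.list(model$fit$coefficients)
  } else if (model$kind == "mean") {
    payload$mean <- model$fit$mean
  } else {
    stop_formbo("oracle models hold arbitrary functions and cannot be serialized",
                "formbo_config_error")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(as.list(obj$spec), class = obj$spec_class)
  feats <- obj$feature_names
  if (obj$kind == "ranger") {
    flds <- obj$trees   # jsonlite simplifies to field -> list of per-tree vectors
    fit <- lapply(seq_along(flds$left), function(i) {
      data.frame(left = as.integer(flds$left[[i]]),
                 right = as.integer(flds$right[[i]]),
                 splitvar = as.integer(flds$splitvar[[i]]),
                 splitval = as.numeric(flds$splitval[[i]]),
                 terminal = as.logical(flds$terminal[[i]]),
                 prediction = as.numeric(flds$prediction[[i]]))
    })
    return(new_fitted_model(spec, feats, "forest_tables", fit, NA_integer_))
  }
  if (obj$kind == "xgboost") {
    fit <- xgboost::xgb.load.raw(charToRaw(obj$booster_json))
    return(new_fitted_model(spec, feats, "xgboost", fit, NA_integer_))
  }
  if (obj$kind == "linear") {
    return(new_fitted_model(spec, feats, "linear",
                            list(coefficients = unlist(obj$coefficients)), NA_integer_))
  }
  if (obj$kind == "mean") {
    return(new_fitted_model(spec, feats, "mean", list(mean = obj$mean), NA_integer_))
  }
  stop_formbo("unrecognized serialized model", "formbo_parse_error")
}

# Route rows through serialized node tables; ranger convention is
# value <= splitval goes to the left child.
predict_forest_tables <- function(trees, M) {
  n <- nrow(M)
  acc <- matrix(0, n, length(trees))
  for (t in seq_along(trees)) {
    tr <- trees[[t]]
    node <- rep(1L, n)               # 1-based into the node table
    active <- !tr$terminal[node]
    while (any(active)) {
      idx <- which(active)
      sv <- tr$splitvar[node[idx]] + 1L
      goes_left <- M[cbind(idx, sv)] <= tr$splitval[node[idx]]
      node[idx] <- ifelse(goes_left, tr$left[node[idx]], tr$right[node[idx]]) + 1L
      active[idx] <- !tr$terminal[node[idx]]
    }
    acc[, t] <- tr$prediction[node]
  }
  rowMeans(acc)
}
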