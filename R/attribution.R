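# Interventional value function: v(S) = mean over background rows of the
# model evaluated with the features in S taken from the instance and the
# rest from the background row. All hybrids for one call are stacked into a
# single predict() so tree models are evaluated in large batches.

hybrid_value <- function(model, instance, background, masks) {
  B <- nrow(background)
  M <- length(instance)
  n_masks <- nrow(masks)
  big <- background[rep(seq_len(B), times = n_masks), , drop = FALSE]
  inst_rep <- matrix(rep(instance, each = B * n_masks), B * n_masks, M)
  mask_rep <- masks[rep(seq_len(n_masks), each = B), , drop = FALSE]
  big[mask_rep] <- inst_rep[mask_rep]
  preds <- predict(model, big)
  as.numeric(tapply(preds, rep(seq_len(n_masks), each = B), mean))
}

prep_background <- function(model, background) {
  bg <- as.data.frame(background)[, model$feature_names, drop = FALSE]
  if (!nrow(bg)) stop_formbo("background must be non-empty", "formbo_config_error")
  as.matrix(bg)
}

prep_instance <- function(model, instance) {
  inst <- as.data.frame(as.list(instance))
  if (is.null(names(instance)) && is.numeric(instance)) {
    inst <- as.data.frame(matrix(instance, nrow = 1))
    names(inst) <- model$feature_names
  }
  as.numeric(inst[1, model$feature_names])
}

#' Exact interventional Shapley attribution
#'
#' Computes the exact Shapley value of every feature for one prediction:
#' \deqn{\phi_i = \sum_{S \subseteq F \setminus \{i\}}
#'   \frac{|S|!\,(M-|S|-1)!}{M!}\,[v(S \cup \{i\}) - v(S)]}
#' with the interventional value function \eqn{v(S)} above. A value of zero
#' means the feature's value does not move the prediction away from the
#' average model output over the background. Enumeration over all
#' \eqn{2^M} subsets is refused beyond `M = 14` features; use
#' [shap_sampled()] there.
#'
#' @param model A `fitted_model`.
#' @param instance Named numeric vector / one-row data frame to explain.
#' @param background Matrix or data frame of background rows.
#' @return An object of class `shap_explanation`: `phi` (named vector,
#'   response units), `base_value` (mean model output over the background)
#'   and `prediction`. Efficiency holds: `sum(phi) + base_value` equals the
#'   prediction to 1e-6.
#' @export
shap_exact <- function(model, instance, background) {
  stopifnot(inherits(model, "fitted_model"))
  bg <- prep_background(model, background)
  x <- prep_instance(model, instance)
  M <- length(x)
  if (M > 14L) {
    stop_formbo("shap_exact enumerates 2^M subsets and refuses M > 14; use shap_sampled()",
                "formbo_config_error")
  }
  n_sub <- bitwShiftL(1L, M)
  masks <- matrix(FALSE, n_sub, M)
  for (i in seq_len(M)) {
    masks[, i] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  }
  colnames(masks) <- model$feature_names
  v <- hybrid_value(model, x, bg, masks)
  sizes <- rowSums(masks)
  lf <- lgamma(seq_len(M + 1))   # lf[k+1] = log(k!)
  phi <- numeric(M)
  subset_ids <- seq_len(n_sub) - 1L
  for (i in seq_len(M)) {
    bit <- bitwShiftL(1L, i - 1L)
    without_i <- bitwAnd(subset_ids, bit) == 0L
    s <- sizes[without_i]
    w <- exp(lf[s + 1] + lf[M - s] - lf[M + 1])
    with_idx <- which(without_i) + bit      # id + bit, back to 1-based
    phi[i] <- sum(w * (v[with_idx] - v[without_i]))
  }
  names(phi) <- model$feature_names
  pred <- predict(model, as.data.frame(matrix(x, 1, M,
                                              dimnames = list(NULL, model$feature_names))))
  structure(list(instance = stats::setNames(x, model$feature_names), phi = phi,
                 base_value = v[1L], prediction = as.numeric(pred),
                 method = "exact"),
            class = "shap_explanation")
}

#' Sampled (permutation) Shapley attribution
#'
#' Unbiased Monte-Carlo estimate of the interventional Shapley values by
#' averaging marginal contributions along random feature orderings. Each
#' permutation's contributions telescope from the background mean to the
#' full prediction, so efficiency holds exactly for any number of
#' permutations; the per-feature values converge to [shap_exact()] as
#' permutations increase.
#'
#' @inheritParams shap_exact
#' @param n_permutations Number of random feature orderings (>= 1).
#' @param seed Integer seed; the same seed reproduces the estimate exactly.
#' @return A `shap_explanation` with `method = "sampled"`.
#' @export
shap_sampled <- function(model, instance, background, n_permutations = 200L, seed = 1L) {
  stopifnot(inherits(model, "fitted_model"), n_permutations >= 1L)
  bg <- prep_background(model, background)
  x <- prep_instance(model, instance)
  M <- length(x)
  perms <- with_local_seed(derive_seed(seed, 5L),
                           lapply(seq_len(n_permutations), function(i) sample.int(M)))
  phi <- numeric(M)
  base <- NA_real_
  for (p in perms) {
    masks <- matrix(FALSE, M + 1L, M)
    for (j in seq_len(M)) masks[j + 1L, p[seq_len(j)]] <- TRUE
    v <- hybrid_value(model, x, bg, masks)
    if (is.na(base)) base <- v[1L]
    phi[p] <- phi[p] + (v[-1L] - v[-(M + 1L)])
  }
  phi <- phi / n_permutations
  names(phi) <- model$feature_names
  pred <- predict(model, as.data.frame(matrix(x, 1, M,
                                              dimnames = list(NULL, model$feature_names))))
  structure(list(instance = stats::setNames(x, model$feature_names), phi = phi,
                 base_value = base, prediction = as.numeric(pred),
                 method = "sampled", n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> (%s) base = %.4g, prediction = %.4g\n",
              x$method, x$base_value, x$prediction))
  print(round(sort(x$phi, decreasing = TRUE), 4))
  invisible(x)
}

# Shapley matrix over many rows; rows of `data` are explained one by one.
shap_matrix <- function(model, data, background, mode = c("auto", "exact", "sampled"),
                        n_permutations = 32L, seed = 1L) {
  mode <- match.arg(mode)
  data <- as.data.frame(data)[, model$feature_names, drop = FALSE]
  M <- length(model$feature_names)
  if (mode == "auto") mode <- if (M <= 10L) "exact" else "sampled"
  out <- matrix(NA_real_, nrow(data), M, dimnames = list(NULL, model$feature_names))
  for (r in seq_len(nrow(data))) {
    ex <- if (mode == "exact") {
      shap_exact(model, data[r, ], background)
    } else {
      shap_sampled(model, data[r, ], background,
                   n_permutations = n_permutations, seed = derive_seed(seed, r))
    }
    out[r, ] <- ex$phi
  }
  out
}

#' Global Shapley ranking
#'
#' Mean absolute Shapley value per feature over a set of rows, ordered by
#' non-increasing importance — the global view used to decide which
#' features of interest drive a screening model.
#'
#' @param model A `fitted_model`.
#' @param data Data frame / matrix of rows to explain (e.g. the training
#'   set or a subsample of it).
#' @param background Background rows for the interventional value function
#'   (defaults to `data`; subsampled to at most `max_background` rows with
#'   the seed).
#' @param mode `"auto"` (exact up to 10 features, sampled beyond),
#'   `"exact"` or `"sampled"`.
#' @param n_permutations Permutations per row in sampled mode.
#' @param seed Integer seed.
#' @param max_background Background subsample cap.
#' @return An object of class `global_shap_ranking`: data frame `ranking`
#'   with columns `feature`, `mean_abs_phi` (sorted), plus the full `phi`
#'   matrix.
#' @export
global_shap <- function(model, data, background = NULL,
                        mode = c("auto", "exact", "sampled"),
                        n_permutations = 32L, seed = 1L, max_background = 100L) {
  data <- as.data.frame(data)
  background <- as.data.frame(background %||% data)
  if (nrow(background) > max_background) {
    idx <- with_local_seed(derive_seed(seed, 17L),
                           sample.int(nrow(background), max_background))
    background <- background[idx, , drop = FALSE]
  }
  phi <- shap_matrix(model, data, background, mode = mode,
                     n_permutations = n_permutations, seed = seed)
  imp <- colMeans(abs(phi))
  ranking <- data.frame(feature = names(imp), mean_abs_phi = unname(imp))
  ranking <- ranking[order(-ranking$mean_abs_phi), ]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, phi = phi, seed = as.integer(seed)),
            class = "global_shap_ranking")
}

#' @export
print.global_shap_ranking <- function(x, ...) {
  cat("<global_shap_ranking>\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Shapley dependence data for one feature
#'
#' One (feature value, phi) pair per row — the data behind a dependence
#' plot, which reveals the shape (monotone, saturating, ...) of a feature's
#' contribution.
#'
#' @inheritParams global_shap
#' @param feature Feature name.
#' @return Data frame with columns `value` and `phi`.
#' @export
shap_dependence <- function(model, data, feature, background = NULL,
                            mode = c("auto", "exact", "sampled"),
                            n_permutations = 32L, seed = 1L, max_background = 100L) {
  if (!feature %in% model$feature_names) {
    stop_formbo(sprintf("unknown feature '%s'", feature), "formbo_config_error")
  }
  gs <- global_shap(model, data, background = background, mode = mode,
                    n_permutations = n_permutations, seed = seed,
                    max_background = max_background)
  data.frame(value = as.data.frame(data)[[feature]], phi = gs$phi[, feature])
}

#' Threshold-based feature selection from a global Shapley ranking
#'
#' Keeps every feature whose mean absolute Shapley value is at least
#' `threshold_fraction` of the largest one; the top feature is always kept,
#' so the selection is never empty.
#'
#' @param ranking A [global_shap()] result.
#' @param threshold_fraction Fraction in (0, 1) of the top importance.
#' @return Character vector of retained feature names (ranking order).
#' @export
select_features <- function(ranking, threshold_fraction = 0.05) {
  stopifnot(inherits(ranking, "global_shap_ranking"))
  if (!is_number(threshold_fraction) || threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop_formbo("threshold_fraction must be in (0, 1)", "formbo_config_error")
  }
  r <- ranking$ranking
  keep <- r$feature[r$mean_abs_phi >= threshold_fraction * max(r$mean_abs_phi)]
  if (!length(keep)) keep <- r$feature[1L]
  keep
}

#' Wrapper feature importance by single-feature (or group) elimination
#'
#' Cross-validates the full model once, then re-runs the identical
#' cross-validation (same seed, hence same folds) with each feature — or
#' named group of features — removed. The drop in out-of-fold \eqn{R^2}
#' relative to the full model measures that feature's influence: the larger
#' the drop, the stronger the feature.
#'
#' @param spec Surrogate specification to cross-validate.
#' @param dataset A [formulation_dataset()].
#' @param groups Named list of character vectors (features removed
#'   together); defaults to one singleton group per feature. Removing a
#'   group is exactly fitting without those columns.
#' @param features Feature set of the full model (default: all).
#' @param k,seed Cross-validation settings shared by every run.
#' @return An object of class `wrapper_report`: `baseline` metrics and a
#'   `rows` data frame (group, rmse_mean, rmse_sd, r2, delta_r2) sorted by
#'   `delta_r2` descending.
#' @export
wrapper_elimination <- function(spec, dataset, groups = NULL, features = NULL,
                                k = 5L, seed = 1L) {
  features <- features %||% feature_names(dataset$space)
  if (is.null(groups)) {
    groups <- stats::setNames(as.list(features), features)
  }
  for (g in groups) {
    if (!length(g) || !all(g %in% features)) {
      stop_formbo("every group must be a non-empty subset of the feature set",
                  "formbo_config_error")
    }
    if (length(setdiff(features, g)) == 0L) {
      stop_formbo("cannot remove all features", "formbo_config_error")
    }
  }
  baseline <- kfold_cv(spec, dataset, features = features, k = k, seed = seed)
  rows <- lapply(names(groups), function(nm) {
    kept <- setdiff(features, groups[[nm]])
    m <- kfold_cv(spec, dataset, features = kept, k = k, seed = seed)
    data.frame(group = nm, rmse_mean = m$rmse_mean, rmse_sd = m$rmse_sd,
               r2 = m$r2, delta_r2 = baseline$r2 - m$r2)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$delta_r2), ]
  rownames(tab) <- NULL
  structure(list(baseline = baseline, rows = tab, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "wrapper_report")
}

#' @export
print.wrapper_report <- function(x, ...) {
  cat(sprintf("<wrapper_report> baseline R^2 = %.3f, RMSE = %.3f +/- %.3f\n",
              x$baseline$r2, x$baseline$rmse_mean, x$baseline$rmse_sd))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Permutation feature importance
#'
#' Degradation of a fitted model's RMSE when one feature column is shuffled
#' (breaking its relation to the response) on evaluation data, averaged over
#' seeded repeats. A feature the model never reads degrades by exactly
#' zero. To avoid optimistic bias, evaluate on data not used for fitting.
#'
#' @param model A `fitted_model`.
#' @param data Evaluation feature data frame/matrix.
#' @param y Observed responses for `data`.
#' @param n_repeats Number of shuffles per feature.
#' @param seed Integer seed.
#' @return An object of class `permutation_importance_report`: data frame
#'   `rows` (feature, mean_increase, sd_increase) sorted by mean RMSE
#'   increase.
#' @export
permutation_importance <- function(model, data, y, n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(model, "fitted_model"), n_repeats >= 1L)
  df <- as.data.frame(data)[, model$feature_names, drop = FALSE]
  base <- rmse(y, predict(model, df))
  rows <- lapply(seq_along(model$feature_names), function(i) {
    f <- model$feature_names[i]
    inc <- vapply(seq_len(n_repeats), function(r) {
      idx <- with_local_seed(derive_seed(seed, i * 1000L + r),
                             sample.int(nrow(df)))
      shuf <- df
      shuf[[f]] <- df[[f]][idx]
      rmse(y, predict(model, shuf)) - base
    }, numeric(1))
    data.frame(feature = f, mean_increase = mean(inc),
               sd_increase = stats::sd(inc))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$mean_increase), ]
  rownames(tab) <- NULL
  structure(list(rows = tab, baseline_rmse = base,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "permutation_importance_report")
}

#' @export
print.permutation_importance_report <- function(x, ...) {
  cat(sprintf("<permutation_importance> baseline RMSE = %.3g, %d repeats\n",
              x$baseline_rmse, x$n_repeats))
  print(x$rows, row.names = FALSE)
  invisible(x)
}
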