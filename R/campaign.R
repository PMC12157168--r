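#' Campaign configuration
#'
#' Settings for the iterative fit / cross-validate / suggest / measure /
#' augment loop.
#'
#' @param budget Maximum number of new observations acquired over the whole
#'   campaign (>= 0; `0` runs a single train-and-validate step).
#' @param batch_size Suggestions per round.
#' @param strategy Acquisition strategy preset (see
#'   [acquisition_config()]).
#' @param kappa Explicit kappa for `strategy = "custom"`.
#' @param r2_target Stop once cross-validated \eqn{R^2} reaches this value
#'   (default 0.9).
#' @param feature_reduction List: `enabled`, `trigger_step` (feature
#'   reduction runs after this many augmentation steps), `threshold_fraction`
#'   (see [select_features()]), `min_features` (only reduce when more
#'   features than this remain), `n_permutations`, `max_rows` (Shapley
#'   sampling effort).
#' @param candidate_specs Surrogate specifications compared by
#'   cross-validation at every step (default: the 30-tree depth-20
#'   randomized ensemble and the linear model).
#' @param replicates Measurements per suggested formulation.
#' @param k Cross-validation folds.
#' @param pool_size Acquisition candidate-pool size.
#' @param seed Master seed; the campaign is bit-reproducible given the seed
#'   and a deterministic oracle.
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(budget = 40L, batch_size = 5L,
                            strategy = "balanced", kappa = NULL,
                            r2_target = 0.9,
                            feature_reduction = list(enabled = TRUE,
                                                     trigger_step = 2L,
                                                     threshold_fraction = 0.05,
                                                     min_features = 10L,
                                                     n_permutations = 16L,
                                                     max_rows = 40L),
                            candidate_specs = list(
                              tree_ensemble_spec("randomized_split_ensemble"),
                              linear_model_spec()),
                            replicates = 1L, k = 5L, pool_size = 2048L,
                            seed = 1L) {
  stopifnot(budget >= 0, batch_size >= 1, r2_target > 0, r2_target <= 1)
  fr <- utils::modifyList(list(enabled = TRUE, trigger_step = 2L,
                               threshold_fraction = 0.05, min_features = 10L,
                               n_permutations = 16L, max_rows = 40L),
                          feature_reduction %||% list())
  structure(list(budget = as.integer(budget), batch_size = as.integer(batch_size),
                 strategy = strategy, kappa = kappa, r2_target = r2_target,
                 feature_reduction = fr, candidate_specs = candidate_specs,
                 replicates = as.integer(replicates), k = as.integer(k),
                 pool_size = as.integer(pool_size), seed = as.integer(seed)),
            class = "campaign_config")
}

#' Stopping rule for a campaign
#'
#' Stop when the cross-validated \eqn{R^2} has reached the target — the
#' model is accurate enough to warrant no further optimization — or when
#' the experimental budget is exhausted.
#'
#' @param metrics An `eval_metrics` (from [kfold_cv()]).
#' @param config A [campaign_config()].
#' @param budget_left Remaining observation budget.
#' @return List with `stop` (flag) and `reason` (`"r2_target"`, `"budget"`
#'   or `"continue"`).
#' @export
stopping_rule <- function(metrics, config, budget_left) {
  stopifnot(inherits(metrics, "eval_metrics"))
  if (metrics$r2 >= config$r2_target) {
    list(stop = TRUE, reason = "r2_target")
  } else if (budget_left <= 0) {
    list(stop = TRUE, reason = "budget")
  } else {
    list(stop = FALSE, reason = "continue")
  }
}

#' Run an iterative optimization campaign
#'
#' Orchestrates the full loop: (1) cross-validate the candidate surrogates
#' on the current data and select the best; (2) log a step record (data
#' size, model type, hyperparameters, RMSE ± sd, R²); (3) if the stopping
#' rule allows, fit the GP on the current feature set, suggest a batch by
#' LCB, "run" the suggested experiments through the oracle (with its
#' measurement noise) and append the new observations; (4) once the
#' configured number of augmentation steps has passed, optionally reduce
#' the feature set by global Shapley importance and continue on the reduced
#' space. The acquisition is always driven by the GP; the tree and linear
#' surrogates serve reporting and attribution.
#'
#' @param initial A non-empty [formulation_dataset()].
#' @param oracle A [ground_truth_oracle()] answering any in-bounds
#'   formulation (for synthetic studies; a lab would substitute real
#'   measurements between steps).
#' @param config A [campaign_config()].
#' @return An object of class `campaign_log`: `steps` (list of step
#'   records), `step_table` (data frame view), `best_trace` (best observed
#'   response per step, monotone in the optimization direction),
#'   `final_model`, `final_features`, `dataset` (augmented), and the
#'   config.
#' @export
run_campaign <- function(initial, oracle, config = campaign_config()) {
  stopifnot(inherits(initial, "formulation_dataset"),
            inherits(oracle, "ground_truth_oracle"))
  if (n_observations(initial) < 2L) {
    stop_formbo("initial dataset must have at least 2 observations", "formbo_config_error")
  }
  space <- initial$space
  minimize <- initial$response_spec$direction == "minimize"
  dataset <- initial
  features <- feature_names(space)
  budget_left <- config$budget
  steps <- list()
  best_trace <- numeric(0)
  augment_steps_done <- 0L
  reduced <- FALSE
  step_idx <- 0L

  repeat {
    step_idx <- step_idx + 1L
    sel <- select_model(config$candidate_specs, dataset, features = features,
                        k = config$k, seed = derive_seed(config$seed, step_idx))
    metrics <- kfold_cv(sel$best, dataset, features = features, k = config$k,
                        seed = derive_seed(config$seed, step_idx))
    y <- dataset_response(dataset)
    best_obs <- if (minimize) min(y) else max(y)
    best_trace <- c(best_trace, best_obs)
    action <- if (step_idx == 1L) "trained" else "augmented"
    decision <- stopping_rule(metrics, config, budget_left)

    # Shapley-based feature reduction after the configured augmentation step
    if (!decision$stop && config$feature_reduction$enabled && !reduced &&
        augment_steps_done >= config$feature_reduction$trigger_step &&
        length(features) > config$feature_reduction$min_features) {
      fr <- config$feature_reduction
      fm <- fit_model(sel$best, dataset_features(dataset, features),
                      dataset_response(dataset),
                      seed = derive_seed(config$seed, 7000L + step_idx))
      Xd <- as.data.frame(dataset_features(dataset, features))
      rows <- Xd
      if (nrow(rows) > fr$max_rows) {
        idx <- with_local_seed(derive_seed(config$seed, 7100L + step_idx),
                               sample.int(nrow(rows), fr$max_rows))
        rows <- rows[idx, , drop = FALSE]
      }
      gs <- global_shap(fm, rows, background = Xd, mode = "sampled",
                        n_permutations = fr$n_permutations,
                        seed = derive_seed(config$seed, 7200L + step_idx),
                        max_background = fr$max_rows)
      features <- select_features(gs, fr$threshold_fraction)
      reduced <- TRUE
      action <- "features_reduced"
      # re-select with the reduced feature set so the log reflects it
      sel <- select_model(config$candidate_specs, dataset, features = features,
                          k = config$k, seed = derive_seed(config$seed, step_idx))
      metrics <- kfold_cv(sel$best, dataset, features = features, k = config$k,
                          seed = derive_seed(config$seed, step_idx))
    }

    steps[[step_idx]] <- list(step_index = step_idx,
                              data_size = n_observations(dataset),
                              model_type = spec_label(sel$best),
                              hyperparameters = spec_hyperparameters(sel$best),
                              metrics = metrics,
                              n_features = length(features),
                              features = features,
                              action = action,
                              best_observed = best_obs)
    if (decision$stop) {
      steps[[step_idx]]$stop_reason <- decision$reason
      break
    }

    # acquisition round, driven by the GP on the current feature set
    sc <- scale_to_unit(dataset, features = features)
    y_fit <- if (minimize) y else -y
    gp <- fit_gp(sc$X, y_fit, seed = derive_seed(config$seed, 500L + step_idx))
    n_new <- min(config$batch_size,
                 max(1L, budget_left %/% config$replicates))
    acq <- acquisition_config(strategy = config$strategy, kappa = config$kappa,
                              batch_size = n_new, pool_size = config$pool_size,
                              seed = derive_seed(config$seed, 900L + step_idx))
    batch <- suggest_batch(gp, space, acq, features = features)
    new_rows <- batch$candidates
    # features dropped by reduction are run at mid-bounds: a lab would hold
    # de-selected excipients at a fixed composition
    full <- setdiff(feature_names(space), feature_names(space, roles = "derived"))
    for (f in setdiff(full, names(new_rows))) {
      b <- feature_bounds(space, f)
      new_rows[[f]] <- mean(b)
    }
    new_rows <- compute_derived(space, new_rows)[, feature_names(space), drop = FALSE]
    measured <- query_oracle(oracle, new_rows, replicates = config$replicates,
                             seed = derive_seed(config$seed, 1300L + step_idx))
    measured$source_tag <- "bo_suggested"
    names(measured)[names(measured) == oracle$response] <- dataset$response
    dataset <- formulation_dataset(space, rbind(dataset$data, measured[, names(dataset$data)]),
                                   dataset$response,
                                   unit = dataset$response_spec$unit,
                                   direction = dataset$response_spec$direction)
    budget_left <- budget_left - nrow(measured)
    augment_steps_done <- augment_steps_done + 1L
  }

  final_model <- fit_model(steps[[length(steps)]]$model_type |>
                             (\(lbl) Find(function(s) spec_label(s) == lbl,
                                          config$candidate_specs))(),
                           dataset_features(dataset, features),
                           dataset_response(dataset),
                           seed = derive_seed(config$seed, 9999L))
  structure(list(steps = steps,
                 step_table = campaign_step_table(steps),
                 best_trace = best_trace,
                 final_model = final_model,
                 final_features = features,
                 dataset = dataset,
                 config = config),
            class = "campaign_log")
}

campaign_step_table <- function(steps) {
  do.call(rbind, lapply(steps, function(s) {
    data.frame(step = s$step_index, data_size = s$data_size,
               model_type = s$model_type,
               hyperparameters = paste(names(s$hyperparameters),
                                       unlist(s$hyperparameters),
                                       sep = "=", collapse = ", "),
               rmse_mean = s$metrics$rmse_mean, rmse_sd = s$metrics$rmse_sd,
               r2 = s$metrics$r2, n_features = s$n_features,
               action = s$action, best_observed = s$best_observed)
  }))
}

#' @export
print.campaign_log <- function(x, ...) {
  cat(sprintf("<campaign_log> %d step(s), final best observed = %.4g\n",
              length(x$steps), x$best_trace[length(x$best_trace)]))
  print(x$step_table, row.names = FALSE)
  invisible(x)
}

#' Write a campaign log to a directory
#'
#' Writes `steps.json` (the step records), `dataset.csv` (the augmented
#' dataset) and `final_model.json`.
#'
#' @param log A `campaign_log`.
#' @param dir Output directory (created if needed).
#' @export
write_campaign <- function(log, dir) {
  stopifnot(inherits(log, "campaign_log"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  steps <- lapply(log$steps, function(s) {
    s$metrics <- list(rmse_mean = s$metrics$rmse_mean, rmse_sd = s$metrics$rmse_sd,
                      r2 = s$metrics$r2, k = s$metrics$k)
    s
  })
  jsonlite::write_json(steps, file.path(dir, "steps.json"),
                       auto_unbox = TRUE, digits = NA)
  write_dataset(log$dataset, file.path(dir, "dataset.csv"))
  if (log$final_model$kind != "oracle") {
    save_model(log$final_model, file.path(dir, "final_model.json"))
  }
  invisible(dir)
}
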