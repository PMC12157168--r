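#' Acquisition configuration
#'
#' Maps a qualitative suggestion strategy onto the exploration/exploitation
#' trade-off parameter \eqn{\kappa} of the lower-confidence-bound
#' acquisition. Low \eqn{\kappa} exploits the surrogate's predicted optimum;
#' high \eqn{\kappa} explores regions of high posterior uncertainty.
#'
#' @param strategy `"exploitation"` (\eqn{\kappa = 0.1}), `"balanced"`
#'   (\eqn{\kappa = 1.96}), `"exploration"` (\eqn{\kappa = 8}), or
#'   `"custom"` with an explicit `kappa`.
#' @param kappa Non-negative trade-off parameter; required for
#'   `strategy = "custom"`, ignored otherwise.
#' @param batch_size Number of experiments to suggest per round.
#' @param pool_size Size of the space-filling candidate pool.
#' @param polish Refine the best pool candidates with a bounded local
#'   optimizer (deterministic); recommended whenever the design space has
#'   more than a few dimensions, where any finite pool is coarse.
#' @param seed Integer seed for pool generation.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(strategy = c("balanced", "exploitation", "exploration", "custom"),
                               kappa = NULL, batch_size = 1L, pool_size = 4096L,
                               polish = TRUE, seed = 1L) {
  strategy <- match.arg(strategy)
  presets <- c(exploitation = 0.1, balanced = 1.96, exploration = 8.0)
  if (strategy == "custom") {
    if (is.null(kappa)) stop_formbo("strategy 'custom' requires kappa", "formbo_config_error")
  } else {
    kappa <- unname(presets[strategy])
  }
  assert_number(kappa, "kappa", lower = 0)
  stopifnot(batch_size >= 1, pool_size >= 1)
  structure(list(strategy = strategy, kappa = kappa,
                 batch_size = as.integer(batch_size),
                 pool_size = as.integer(pool_size),
                 polish = isTRUE(polish), seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Lower confidence bound
#'
#' \eqn{\mathrm{LCB}(x) = \mu(x) - \kappa\,\sigma(x)}. The engine always
#' minimizes LCB; responses to be maximized are negated before fitting, so
#' minimizing LCB is correct for either direction.
#'
#' @param mean Posterior mean(s) \eqn{\mu}.
#' @param var Posterior variance(s) \eqn{\sigma^2}.
#' @param kappa Non-negative trade-off parameter \eqn{\kappa}.
#' @return Numeric acquisition value(s); lower is better.
#' @export
lcb <- function(mean, var, kappa) {
  assert_number(kappa, "kappa", lower = 0)
  if (any(var < 0)) stop_formbo("variance must be non-negative", "formbo_domain_error")
  mean - kappa * sqrt(var)
}

#' Seeded space-filling candidate pool
#'
#' Draws a Latin-hypercube pool over the design-space bounds and rejects
#' rows violating linear constraints (resampling until the pool is filled).
#' Derived features are recomputed from their parents. Deterministic given
#' `seed`.
#'
#' @param space A [design_space()].
#' @param n Pool size.
#' @param seed Integer seed.
#' @return Data frame of `n` in-bounds, constraint-satisfying formulations
#'   (original units, all features including derived).
#' @export
candidate_pool <- function(space, n, seed = 1L) {
  sample_design(space, n, scheme = "latin", seed = seed)
}

#' Suggest the next batch of experiments
#'
#' Scores a seeded candidate pool with the lower-confidence-bound
#' acquisition under the fitted GP surrogate and returns the best
#' `batch_size` formulations under a constant-liar batch rule: after each
#' selection the GP is temporarily augmented with the selected point and its
#' predicted mean, so later selections avoid duplicating earlier ones.
#' Optionally each selection is refined by a bounded quasi-Newton descent of
#' the acquisition surface started from the best pool candidates (results
#' violating constraints fall back to the pool optimum). Fully deterministic
#' given `config$seed`.
#'
#' @param state A [fit_gp()] result trained on unit-scaled features of
#'   `space` (in design-space order).
#' @param space The [design_space()].
#' @param config An [acquisition_config()].
#' @param features Names of the features the GP was trained on (defaults to
#'   all design-space features). Non-derived features not in this set are
#'   held at mid-bounds for constraint checks.
#' @return An object of class `suggestion_batch`: a list with `candidates`
#'   (data frame in original units), `acquisition_values`, `strategy_used`,
#'   `kappa` and `seed`.
#' @export
suggest_batch <- function(state, space, config = acquisition_config(),
                          features = NULL) {
  stopifnot(inherits(state, "gp_fit"), inherits(space, "design_space"),
            inherits(config, "acquisition_config"))
  features <- features %||% feature_names(space)
  if (length(features) != ncol(state$X)) {
    stop_formbo("GP dimensionality does not match the feature set", "formbo_config_error")
  }
  free <- setdiff(features, feature_names(space, roles = "derived"))
  pool <- candidate_pool(space, config$pool_size, seed = config$seed)
  if (!nrow(pool)) stop_formbo("candidate pool empty after constraint rejection",
                               "formbo_feasibility_error")

  # Map a matrix of free (non-derived) unit-scaled coords to the full
  # unit-scaled feature matrix the GP expects (derived = scaled parent sum).
  # When the model features are exactly the free features the map is the
  # identity, which keeps the inner acquisition loop pure matrix math.
  b_free <- feature_bounds(space, free)
  simple <- identical(features, free)
  to_model_units <- function(Ufree) {
    if (simple) return(Ufree)
    orig <- sweep(sweep(Ufree, 2, b_free[, "upper"] - b_free[, "lower"], "*"),
                  2, b_free[, "lower"], "+")
    colnames(orig) <- free
    df <- as.data.frame(orig)
    df <- compute_derived(space, df)
    unit_scale_matrix(space, as.matrix(df[, features, drop = FALSE]), features)
  }
  score <- function(Ufree) {
    p <- predict_gp(gp, to_model_units(Ufree))
    lcb(p$mean, p$var, config$kappa)
  }
  unconstrained <- length(space$constraints) == 0L

  U_pool <- unit_scale_matrix(space, as.matrix(pool[, free, drop = FALSE]), free)
  gp <- state
  chosen <- list(); chosen_acq <- numeric(0)
  for (b in seq_len(config$batch_size)) {
    acq <- score(U_pool)
    ord <- order(acq)
    u_best <- U_pool[ord[1L], , drop = FALSE]
    a_best <- acq[ord[1L]]
    if (config$polish) {
      n_starts <- min(2L, length(ord))
      for (s in seq_len(n_starts)) {
        u0 <- U_pool[ord[s], ]
        d <- length(u0)
        num_grad <- function(u) {
          # batched central differences: one vectorized GP call per gradient
          eps <- 1e-6
          U <- matrix(rep(u, each = 2 * d), 2 * d, d)
          idx <- cbind(seq_len(2 * d), rep(seq_len(d), each = 2))
          U[idx] <- U[idx] + rep(c(eps, -eps), d)
          U <- pmin(pmax(U, 0), 1)
          f <- score(U)
          (f[seq(1, 2 * d, 2)] - f[seq(2, 2 * d, 2)]) /
            (U[cbind(seq(1, 2 * d, 2), seq_len(d))] - U[cbind(seq(2, 2 * d, 2), seq_len(d))])
        }
        res <- tryCatch(
          stats::optim(u0, fn = function(u) score(matrix(u, nrow = 1)),
                       gr = num_grad,
                       method = "L-BFGS-B", lower = rep(0, length(u0)),
                       upper = rep(1, length(u0)), control = list(maxit = 40)),
          error = function(e) NULL)
        if (is.null(res)) next
        if (!unconstrained) {
          cand_df <- as.data.frame(to_free_orig(res$par, b_free, free))
          cand_df <- compute_derived(space, cand_df)
          if (!satisfies_constraints(space, cand_df)) next
        }
        if (res$value < a_best) { a_best <- res$value; u_best <- matrix(res$par, nrow = 1) }
      }
    }
    row_orig <- as.data.frame(to_free_orig(drop(u_best), b_free, free))
    row_orig <- compute_derived(space, row_orig)
    chosen[[b]] <- row_orig[, features, drop = FALSE]
    chosen_acq[b] <- a_best
    if (b < config$batch_size) {
      # constant liar: pretend the predicted mean was observed there
      xm <- unit_scale_matrix(space, as.matrix(row_orig[, features, drop = FALSE]), features)
      lie <- predict_gp(gp, xm)$mean
      gp <- gp_augment(gp, xm, lie)
    }
  }
  cands <- do.call(rbind, chosen)
  rownames(cands) <- NULL
  structure(list(candidates = cands, acquisition_values = chosen_acq,
                 strategy_used = config$strategy, kappa = config$kappa,
                 seed = config$seed),
            class = "suggestion_batch")
}

to_free_orig <- function(u, b_free, free) {
  m <- matrix(u, nrow = 1)
  out <- sweep(sweep(m, 2, b_free[, "upper"] - b_free[, "lower"], "*"),
               2, b_free[, "lower"], "+")
  colnames(out) <- free
  out
}

#' @export
print.suggestion_batch <- function(x, ...) {
  cat(sprintf("<suggestion_batch> %d candidate(s), strategy '%s' (kappa = %.3g)\n",
              nrow(x$candidates), x$strategy_used, x$kappa))
  print(cbind(x$candidates, acquisition = x$acquisition_values), row.names = FALSE)
  invisible(x)
}

#' Write a suggestion batch as CSV
#'
#' @param batch A `suggestion_batch`.
#' @param path Output path; candidates plus an `acquisition` column.
#' @export
write_suggestions <- function(batch, path) {
  stopifnot(inherits(batch, "suggestion_batch"))
  utils::write.csv(cbind(batch$candidates, acquisition = batch$acquisition_values),
                   path, row.names = FALSE)
  invisible(path)
}
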