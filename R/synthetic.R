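#' Parameters of the synthetic titer-loss landscape
#'
#' Defines a ground-truth surface for the stability readout of a liquid
#' live-virus formulation screen: infectious titer loss (log10 PFU/mL) after
#' accelerated incubation, as a function of excipient concentrations and the
#' starting titer of the batch. The surface encodes the qualitative
#' structure such screens exhibit:
#' * a protective residual-albumin effect that saturates at a knee
#'   (default 0.2 mg/mL) — concentrations below the knee raise the loss;
#' * a destabilizing spiked-albumin effect saturating at its own knee
#'   (default 2 mg/mL) — beyond it, more albumin does not further increase
#'   the loss;
#' * linear effects for other designed excipients, one curved (quadratic)
#'   excipient with an interior optimum, one pairwise interaction, and a
#'   weak starting-titer covariate effect;
#' * a configurable number of null features with no effect at all.
#'
#' Saturations are piecewise linear, so knee locations are unambiguous
#' ground truth for attribution tests. The assay noise default (0.1 log10)
#' is a plausible plaque-assay precision.
#'
#' @param baseline_loss Loss at the reference formulation (all effects at
#'   zero), log10 PFU/mL.
#' @param residual_knee,residual_effect Knee (mg/mL) and full effect size
#'   (log10) of the protective residual-albumin term.
#' @param spiked_knee,spiked_effect Knee (mg/mL) and full effect size
#'   (log10) of the destabilizing spiked-albumin term.
#' @param linear_coeffs Named loss-per-(mg/mL) coefficients of the other
#'   designed excipients.
#' @param quadratic_feature List `(name, optimum, curvature)` for the curved
#'   excipient.
#' @param interaction List `(pair, coefficient)` for one pairwise product
#'   term.
#' @param n_null_features Number of inert excipient features.
#' @param starting_titer_range Starting-titer bounds, log10 PFU/mL.
#' @param starting_titer_coeff Loss increase per log10 of starting titer
#'   above the lower bound.
#' @param noise_sd Assay noise standard deviation, log10 PFU/mL.
#' @param replicates Default number of measurement replicates.
#' @return An object of class `titer_landscape_params`.
#' @export
titer_landscape_params <- function(baseline_loss = 1.5,
                                   residual_knee = 0.2, residual_effect = 0.8,
                                   spiked_knee = 2.0, spiked_effect = 0.4,
                                   linear_coeffs = c(excipient_A = 0.03,
                                                     excipient_B = 0.025,
                                                     excipient_C = 0.08,
                                                     excipient_E = 0.02,
                                                     excipient_I = -0.04),
                                   quadratic_feature = list(name = "excipient_D",
                                                            optimum = 4, curvature = 0.01),
                                   interaction = list(pair = c("excipient_A", "excipient_B"),
                                                      coefficient = 0.002),
                                   n_null_features = 10L,
                                   starting_titer_range = c(6.9, 7.9),
                                   starting_titer_coeff = 0.05,
                                   noise_sd = 0.1, replicates = 2L) {
  stopifnot(residual_knee > 0, spiked_knee > 0, noise_sd >= 0, replicates >= 1)
  structure(
    list(baseline_loss = baseline_loss,
         residual_knee = residual_knee, residual_effect = residual_effect,
         spiked_knee = spiked_knee, spiked_effect = spiked_effect,
         linear_coeffs = linear_coeffs, quadratic_feature = quadratic_feature,
         interaction = interaction, n_null_features = as.integer(n_null_features),
         starting_titer_range = starting_titer_range,
         starting_titer_coeff = starting_titer_coeff,
         noise_sd = noise_sd, replicates = as.integer(replicates)),
    class = "titer_landscape_params"
  )
}

#' Synthetic titer-loss landscape (design space, oracle, known optimum)
#'
#' Bundles the design space of the liquid-formulation screen (by default 19
#' features: residual and spiked albumin, starting titer, six designed
#' excipients and ten nulls) with its ground-truth oracle and the analytic
#' optimum of the noiseless surface.
#'
#' @param params A [titer_landscape_params()].
#' @return An object of class `synthetic_landscape` with elements `space`,
#'   `params`, `oracle`, `designed_features`, `null_features`,
#'   `true_minimum` (value) and `true_argmin` (one-row data frame).
#' @export
titer_landscape <- function(params = titer_landscape_params()) {
  feats <- list(
    feature_spec("residual_rHSA", 0, 1.5, "mg/mL"),
    feature_spec("spiked_rHSA", 0, 15, "mg/mL")
  )
  for (nm in names(params$linear_coeffs)) {
    feats <- c(feats, list(feature_spec(nm, 0, 10, "mg/mL")))
  }
  q <- params$quadratic_feature
  if (!is.null(q)) feats <- c(feats, list(feature_spec(q$name, 0, 10, "mg/mL")))
  feats <- c(feats, list(feature_spec("starting_titer",
                                      params$starting_titer_range[1],
                                      params$starting_titer_range[2],
                                      "log10 PFU/mL", role = "covariate")))
  if (params$n_null_features > 0) {
    for (i in seq_len(params$n_null_features)) {
      feats <- c(feats, list(feature_spec(sprintf("null_%02d", i), 0, 10, "mg/mL")))
    }
  }
  space <- design_space(feats)
  designed <- c("residual_rHSA", "spiked_rHSA", names(params$linear_coeffs),
                if (!is.null(q)) q$name, "starting_titer")

  # Analytic optimum: each additive term minimized independently.
  arg <- as.data.frame(as.list(stats::setNames(rep(0, length(feature_names(space))),
                                               feature_names(space))))
  # any residual at/above the knee is optimal; take the plateau midpoint so
  # "the optimum" is a well-conditioned representative of the optimal set
  arg$residual_rHSA <- (params$residual_knee + 1.5) / 2
  arg$spiked_rHSA <- 0
  for (nm in names(params$linear_coeffs)) {
    arg[[nm]] <- if (params$linear_coeffs[[nm]] > 0) 0 else 10
  }
  if (!is.null(q)) arg[[q$name]] <- q$optimum
  arg$starting_titer <- params$starting_titer_range[1]
  truth_min <- titer_loss_truth(params, arg)

  oracle <- ground_truth_oracle(
    truth = function(df) titer_loss_truth(params, df),
    noise_sd = params$noise_sd, direction = "minimize",
    name = "synthetic_titer_loss", unit = "log10 PFU/mL",
    response = "titer_loss"
  )
  structure(list(space = space, params = params, oracle = oracle,
                 designed_features = designed,
                 null_features = setdiff(feature_names(space), designed),
                 true_minimum = truth_min, true_argmin = arg),
            class = "synthetic_landscape")
}

#' Noiseless titer loss of the synthetic landscape
#'
#' @param params A [titer_landscape_params()].
#' @param formulations Data frame (or one-row list) of feature values.
#' @return Numeric vector of noiseless losses, clipped at zero from below.
#' @export
titer_loss_truth <- function(params, formulations) {
  df <- as.data.frame(formulations)
  need <- c("residual_rHSA", "spiked_rHSA", names(params$linear_coeffs))
  q <- params$quadratic_feature
  if (!is.null(q)) need <- c(need, q$name)
  need <- c(need, "starting_titer")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_formbo(paste0("missing feature(s): ", paste(miss, collapse = ", ")),
                "formbo_schema_error")
  }
  loss <- rep(params$baseline_loss, nrow(df))
  loss <- loss - params$residual_effect *
    pmin(df$residual_rHSA, params$residual_knee) / params$residual_knee
  loss <- loss + params$spiked_effect *
    pmin(df$spiked_rHSA, params$spiked_knee) / params$spiked_knee
  for (nm in names(params$linear_coeffs)) {
    loss <- loss + params$linear_coeffs[[nm]] * df[[nm]]
  }
  if (!is.null(q)) loss <- loss + q$curvature * (df[[q$name]] - q$optimum)^2
  it <- params$interaction
  if (!is.null(it)) loss <- loss + it$coefficient * df[[it$pair[1]]] * df[[it$pair[2]]]
  loss <- loss + params$starting_titer_coeff *
    (df$starting_titer - params$starting_titer_range[1])
  pmax(loss, 0)
}

#' Parameters of the synthetic freeze-concentrate glass-transition landscape
#'
#' Ground truth for the freeze-dried-formulation screen: the glass
#' transition temperature of the maximally freeze-concentrated solution
#' (Tg', in deg C) of a multi-solute formulation, modeled with the Fox
#' mixture rule on absolute temperature,
#' \deqn{1/T_{mix} = \sum_i w_i / T_i,}
#' with \eqn{w_i} the solute mass fractions, optionally plus pairwise
#' non-ideality terms \eqn{\sum_{i<j} k_{ij} w_i w_j} that emulate the
#' component interactions for which simple mixture rules are known to
#' deviate. Component Tg' values other than the polymer's are synthetic
#' placeholders for anonymized excipients. The noise default (1.5 deg C)
#' reads the +/- 3 deg C determination figure of differential scanning
#' calorimetry as a roughly two-standard-deviation envelope.
#'
#' @param components Data frame with columns `name`, `tg` (component Tg',
#'   deg C, in (-80, 0)), `lower`, `upper` (concentration bounds, mg/mL).
#' @param deviation_terms Optional data frame with columns `a`, `b`
#'   (component names) and `k` (deg C coefficient on \eqn{w_a w_b}).
#' @param noise_sd Measurement noise standard deviation, deg C.
#' @param replicates Default replicate count.
#' @return An object of class `tg_mixture_params`.
#' @export
tg_mixture_params <- function(components = data.frame(
                                name = c("pvp", "dextran", "sucrose", "trehalose",
                                         "sorbitol", "proline", "arginine",
                                         "histidine", "phosphate_buffer"),
                                tg = c(-26, -11, -32, -29.5, -44, -52, -44, -33, -55),
                                lower = rep(0, 9),
                                upper = c(60, 60, 100, 100, 60, 40, 40, 20, 20),
                                stringsAsFactors = FALSE),
                              deviation_terms = NULL,
                              noise_sd = 1.5, replicates = 2L) {
  stopifnot(all(c("name", "tg", "lower", "upper") %in% names(components)),
            all(components$tg > -80), all(components$tg < 0), noise_sd >= 0)
  structure(list(components = components, deviation_terms = deviation_terms,
                 noise_sd = noise_sd, replicates = as.integer(replicates)),
            class = "tg_mixture_params")
}

#' Noiseless Tg' of a multi-solute formulation (Fox rule)
#'
#' @param params A [tg_mixture_params()].
#' @param formulations Data frame of component concentrations (mg/mL), one
#'   column per component.
#' @return Numeric vector of Tg' values in deg C. A single-component
#'   formulation returns that component's Tg' exactly.
#' @export
tg_truth <- function(params, formulations) {
  df <- as.data.frame(formulations)
  comps <- params$components
  miss <- setdiff(comps$name, names(df))
  if (length(miss)) {
    stop_formbo(paste0("missing component(s): ", paste(miss, collapse = ", ")),
                "formbo_schema_error")
  }
  C <- as.matrix(df[, comps$name, drop = FALSE])
  total <- rowSums(C)
  if (any(total <= 0)) {
    stop_formbo("undefined mixture: total solute concentration must be > 0",
                "formbo_domain_error")
  }
  W <- C / total
  TK <- comps$tg + 273.15
  inv_t <- as.numeric(W %*% (1 / TK))
  tg <- 1 / inv_t - 273.15
  dev <- params$deviation_terms
  if (!is.null(dev)) {
    for (i in seq_len(nrow(dev))) {
      tg <- tg + dev$k[i] * W[, dev$a[i]] * W[, dev$b[i]]
    }
  }
  tg
}

#' Synthetic glass-transition landscape
#'
#' @param params A [tg_mixture_params()].
#' @param min_total Lower bound (mg/mL) on total solute enforced as a
#'   constraint so every formulation has a defined freeze concentrate.
#' @return A `synthetic_landscape` (direction `"maximize"`) whose
#'   `true_maximum` is attained by the all-highest-Tg'-component corner.
#' @export
tg_landscape <- function(params = tg_mixture_params(), min_total = 5) {
  comps <- params$components
  feats <- lapply(seq_len(nrow(comps)), function(i) {
    feature_spec(comps$name[i], comps$lower[i], comps$upper[i], "mg/mL")
  })
  cons <- list(linear_constraint(
    stats::setNames(rep(-1, nrow(comps)), comps$name), rhs = -min_total))
  space <- design_space(feats, constraints = cons)
  oracle <- ground_truth_oracle(
    truth = function(df) tg_truth(params, df),
    noise_sd = params$noise_sd, direction = "maximize",
    name = "synthetic_tg", unit = "deg C", response = "tg_prime"
  )
  best <- comps$name[which.max(comps$tg)]
  arg <- as.data.frame(as.list(stats::setNames(rep(0, nrow(comps)), comps$name)))
  arg[[best]] <- comps$upper[comps$name == best]
  structure(list(space = space, params = params, oracle = oracle,
                 designed_features = comps$name, null_features = character(),
                 true_maximum = max(comps$tg), true_argmax = arg),
            class = "synthetic_landscape")
}

#' Ground-truth oracle
#'
#' Wraps a deterministic noiseless response function with a Gaussian noise
#' model, so campaigns can "run" suggested experiments in silico. Repeated
#' queries with the same seed reproduce identical noisy values.
#'
#' @param truth Function mapping a data frame of formulations to noiseless
#'   responses.
#' @param noise_sd Measurement noise standard deviation.
#' @param direction `"minimize"` or `"maximize"`.
#' @param name,unit,response Labels for logs and generated datasets.
#' @return An object of class `ground_truth_oracle`.
#' @export
ground_truth_oracle <- function(truth, noise_sd = 0,
                                direction = c("minimize", "maximize"),
                                name = "oracle", unit = "", response = "response") {
  direction <- match.arg(direction)
  stopifnot(is.function(truth), noise_sd >= 0)
  structure(list(truth = truth, noise_sd = noise_sd, direction = direction,
                 name = name, unit = unit, response = response),
            class = "ground_truth_oracle")
}

#' Query an oracle with measurement noise
#'
#' @param oracle A [ground_truth_oracle()].
#' @param formulations Data frame of formulations.
#' @param replicates Replicate measurements per formulation.
#' @param seed Integer seed for the noise draws.
#' @return Data frame: the formulations replicated `replicates` times with
#'   columns `replicate_id` and the oracle's response.
#' @export
query_oracle <- function(oracle, formulations, replicates = 1L, seed = 1L) {
  stopifnot(inherits(oracle, "ground_truth_oracle"), replicates >= 1)
  df <- as.data.frame(formulations)
  truth <- oracle$truth(df)
  out <- df[rep(seq_len(nrow(df)), each = replicates), , drop = FALSE]
  out$replicate_id <- rep(seq_len(replicates), times = nrow(df))
  noise <- with_local_seed(derive_seed(seed, 7L),
                           stats::rnorm(nrow(out), 0, oracle$noise_sd))
  out[[oracle$response]] <- rep(truth, each = replicates) + noise
  rownames(out) <- NULL
  out
}

#' Space-filling designs over a design space
#'
#' @param space A [design_space()].
#' @param n Number of formulations.
#' @param scheme `"latin"` (Latin hypercube; each dimension stratified into
#'   `n` equal slices) or `"uniform"` (independent uniform draws).
#' @param seed Integer seed.
#' @return Data frame of `n` in-bounds formulations satisfying all
#'   constraints, with derived features computed.
#' @export
sample_design <- function(space, n, scheme = c("latin", "uniform"), seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(space, "design_space"), n >= 1)
  free <- setdiff(feature_names(space), feature_names(space, roles = "derived"))
  b <- feature_bounds(space, free)
  draw <- function(m, stream) {
    U <- with_local_seed(derive_seed(seed, stream), {
      if (scheme == "latin") lhs::randomLHS(m, length(free))
      else matrix(stats::runif(m * length(free)), m, length(free))
    })
    orig <- sweep(sweep(U, 2, b[, "upper"] - b[, "lower"], "*"), 2, b[, "lower"], "+")
    colnames(orig) <- free
    compute_derived(space, as.data.frame(orig))
  }
  df <- draw(n, 0L)
  keep <- df[satisfies_constraints(space, df), , drop = FALSE]
  tries <- 1L
  while (nrow(keep) < n && tries <= 50L) {
    extra <- draw(max(n, 64L), tries)
    extra <- extra[satisfies_constraints(space, extra), , drop = FALSE]
    keep <- rbind(keep, extra)
    tries <- tries + 1L
  }
  if (nrow(keep) < n) {
    stop_formbo("constraints appear infeasible: could not fill the design",
                "formbo_feasibility_error")
  }
  out <- keep[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out[, feature_names(space), drop = FALSE]
}

#' Generate a noisy synthetic screening dataset
#'
#' Samples formulations (unless given), queries the landscape's oracle with
#' replicate measurement noise, and packages the result as a
#' [formulation_dataset()] tagged `source_tag = "synthetic"`.
#'
#' @param landscape A `synthetic_landscape` (from [titer_landscape()] or
#'   [tg_landscape()]).
#' @param n Number of distinct formulations to sample (ignored when
#'   `formulations` is given).
#' @param formulations Optional data frame of formulations to measure.
#' @param replicates Replicates per formulation (default from the landscape
#'   parameters).
#' @param scheme Sampling scheme for [sample_design()].
#' @param seed Integer seed (design and noise).
#' @return A `formulation_dataset`; the noiseless truth per row is attached
#'   as attribute `"truth"` for testing.
#' @export
generate_dataset <- function(landscape, n = 100L, formulations = NULL,
                             replicates = NULL, scheme = "latin", seed = 1L) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  replicates <- replicates %||% landscape$params$replicates
  if (is.null(formulations)) {
    formulations <- sample_design(landscape$space, n, scheme = scheme,
                                  seed = derive_seed(seed, 1L))
  }
  measured <- query_oracle(landscape$oracle, formulations,
                           replicates = replicates, seed = derive_seed(seed, 2L))
  measured$source_tag <- "synthetic"
  ds <- formulation_dataset(landscape$space, measured, landscape$oracle$response,
                            unit = landscape$oracle$unit,
                            direction = landscape$oracle$direction)
  attr(ds, "truth") <- rep(landscape$oracle$truth(as.data.frame(formulations)),
                           each = replicates)
  ds
}
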