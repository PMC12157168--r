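---
title: "Model-guided formulation development with formbo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-guided formulation development with formbo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formbo)
```

## The problem

Stabilizing a biologic — here, live-virus vaccine candidates — means finding
excipient compositions that keep a critical quality attribute within
specification: the infectious-titer loss of a liquid formulation after
accelerated incubation (to be minimized, in log10 PFU/mL), or the glass
transition temperature of the maximally freeze-concentrated solution (Tg',
in °C, to be maximized so freeze-drying stays efficient and collapse-free).
Each measurement is a wet-lab experiment, the design space has ten to twenty
continuous dimensions, and responses are non-linear with saturation effects,
so classical one-factor-at-a-time screening and small factorial designs use
the budget poorly.

`formbo` implements the model-guided alternative: fit a probabilistic
surrogate to all data acquired so far, let an acquisition function propose
the next experiments, measure, augment, and repeat until the model is
accurate enough or the budget is gone. Alongside the optimizer it provides
the reporting and interpretation layer such campaigns need in practice:
cross-validated model quality, holdout validation, Shapley / permutation /
wrapper feature importance, and response-surface maps with operating-zone
extraction.

## The surrogate and the acquisition

The engine's surrogate is a Gaussian process with constant mean and an
isotropic Matérn 5/2 kernel on unit-scaled inputs,

$$K(x, x') = s^2\left(1 + \frac{\sqrt5\,d}{\ell} +
  \frac{5 d^2}{3\ell^2}\right)\exp\!\left(-\frac{\sqrt5\,d}{\ell}\right),
  \qquad d = \lVert x - x' \rVert,$$

with signal variance $s^2$, length-scale $\ell$, and Gaussian observation
noise $\sigma_n^2$. The 5/2 smoothness is fixed: physical response surfaces
are typically twice differentiable but not analytic, and this choice makes
the kernel's behavior a modeling commitment rather than a tuning knob. A
single isotropic length-scale is the default — bounds-scaling puts all
features on $[0,1]$, so one $\ell$ is meaningful across units (mg/mL,
% w/v, log10 PFU/mL). Responses are standardized internally; predictions
are de-standardized.

Hyperparameters maximize the log marginal likelihood by L-BFGS-B from eight
seeded starts over $\log \ell \in [\log 10^{-2}, \log 10]$,
$\log s^2 \in [\log 10^{-3}, \log 10^{3}]$,
$\log \sigma_n^2 \in [\log 10^{-8}, \log 10]$, with analytic gradients.
Replicated formulations make the Gram matrix numerically singular when the
noise is small, so factorization adds an escalating jitter
($10^{-10}$ to $10^{-6}$). The GP is refit at every campaign step.

Candidate experiments are scored by the lower confidence bound,
$\mathrm{LCB}(x) = \mu(x) - \kappa\,\sigma(x)$, minimized internally
(maximize-direction responses are negated at the engine boundary). The
strategy presets map to $\kappa$: exploitation 0.1, balanced 1.96,
exploration 8. The preset values are package choices — 1.96 is the familiar
95% normal quantile, 0.1 and 8 are chosen to make the two extremes behave
as their names promise on unit-variance standardized responses.

### Optimizing the acquisition

Suggestions are drawn from a seeded Latin-hypercube candidate pool
(default 4096) filtered by the design space's linear constraints — the
guard against physically nonsensical proposals such as concentrations
beyond solubility. A finite pool alone, however, is too coarse once the
space has many dimensions: the expected best of a 4096-point random pool on
the package's default 19-feature synthetic landscape sits several tenths of
a log above the true optimum, simply because random points never land near
a high-dimensional corner. Each selected candidate is therefore refined by
a bounded quasi-Newton (L-BFGS-B) descent of the acquisition surface
started from the best pool points, using batched central-difference
gradients. The refinement is deterministic, so suggestion batches remain
bit-reproducible given the seed. Batches use the constant-liar rule: after
each selection the GP is temporarily augmented with the candidate and its
predicted mean before the next selection, which keeps batch members
distinct and spread.

## Reporting surrogates

The campaign's reporting models mirror common screening practice:

* a randomized-split tree ensemble (extremely randomized trees: full sample
  per tree, all features candidate at each split, one uniform random
  threshold per candidate, best split by variance reduction) with fixed
  screening-scale hyperparameters — 30 trees, depth 20. Hyperparameters are
  deliberately not tuned, so model-quality changes across campaign steps
  reflect the data, not the tuner. Backed by `ranger`.
* gradient-boosted trees (depth 3, 100 rounds, learning rate 0.1, L2
  penalty 1), backed by `xgboost`.
* ordinary least squares as the linear baseline.

`select_model()` cross-validates every candidate on identical folds and
picks the lowest mean RMSE, breaking ties toward the simpler family.
Training rows are canonically sorted before fitting so fits are invariant
to row order; all randomness is consumed at fit time from a single seed.
Fitted models serialize to JSON (ensembles as explicit node tables) and
reload bit-compatibly.

Because trees provide no native predictive variance, the acquisition is
always GP-driven; tree models serve reporting and attribution.

## Evaluation conventions

`kfold_cv()` shuffles once with the seed and cuts contiguous folds
(default k = 5, a single repetition). Fold RMSEs are reported as
mean ± population standard deviation across folds; $R^2$ is computed once
on pooled out-of-fold predictions, which avoids the instability of
per-fold $R^2$ on small folds. `holdout_accuracy()` counts a prediction
correct when its absolute error is within a user-chosen tolerance — there
is no universal value; the assay's own variability is the natural choice,
and the package's synthetic checks use twice the generator's noise
standard deviation. Prediction-error tables report signed
`delta = predicted − observed`.

## Feature attribution

Shapley values use the interventional value function: $v(S)$ is the mean
model output over a background sample with the features in $S$ taken from
the instance. `shap_exact()` enumerates all $2^M$ subsets (refused above
$M = 14$, where the enumeration stops being desk-scale); `shap_sampled()`
averages marginal contributions along seeded random feature orderings —
each ordering telescopes, so the efficiency identity
$\sum_i \phi_i + \mathrm{base} = \mathrm{prediction}$ holds for any number
of permutations. Global importance is the mean $|\phi|$ over a row sample;
`select_features()` keeps features above a fraction (default 0.05) of the
top importance. Wrapper elimination re-runs the identical cross-validation
with each feature (or group) removed and ranks by the drop in $R^2$;
permutation importance reports the RMSE increase under seeded column
shuffles on caller-supplied evaluation data — use held-out data to avoid
optimistic bias.

## The synthetic landscapes

Real screening datasets for these products are proprietary, so the package
ships ground-truth generators that emulate their statistical structure and
make every pipeline stage testable end to end.

**Titer-loss landscape** (19 features by default): a protective
residual-albumin effect that saturates at a knee (0.2 mg/mL, full effect
0.8 log10 — below the knee, losses rise), a destabilizing spiked-albumin
effect saturating at 2 mg/mL (full effect 0.4 log10), linear effects for
five designed excipients (the dominant one at 0.08 log10 per mg/mL over
0–10 mg/mL), one curved excipient with an interior optimum (quadratic,
optimum 4 mg/mL), one weak pairwise interaction, a weak starting-titer
covariate (0.05 log10 per log10 over 6.9–7.9), and ten null features.
Saturations are piecewise linear so knee locations are unambiguous ground
truth. Assay noise is Gaussian with sd 0.1 log10 — a plausible
plaque-assay precision — and measurements default to duplicates. The
noiseless minimum (0.3 log10) and its location are analytic, which gives
optimization tests an exact target.

**Glass-transition landscape** (nine solutes): Tg' follows the Fox mixture
rule on absolute temperature, $1/T_{mix} = \sum_i w_i/T_i$ with solute mass
fractions $w_i$, optionally plus pairwise non-ideality terms of the
Gordon–Taylor kind. The polymer component's Tg' (−26 °C for PVP) is a
literature value; the remaining component values are synthetic placeholders
for anonymized excipients. Noise defaults to 1.5 °C, reading the ±3 °C
determination precision of differential scanning calorimetry as roughly a
two-standard-deviation envelope. A minimum-total-solute constraint keeps
every sampled formulation's freeze concentrate well defined.

What the generators deliberately do not emulate: assay drift and batch
effects, censored titer measurements at the assay's limit of detection,
correlated excipient doses from stock-solution designs, and any mechanistic
degradation kinetics. Passing tests on these landscapes therefore
demonstrate that the machinery recovers known structure under honest noise
— not that any particular real formulation behaves this way.

## Numerical and design choices worth knowing

* Feature scaling is affine from design-space bounds; the inverse map is
  exact to 1e-12. Out-of-bounds historical data warn rather than fail by
  default, because legacy screens often predate the current bounds.
* Derived features are parent sums (the one combiner screening reports
  use, e.g. total albumin = residual + spiked); they are recomputed, never
  stored independently.
* The GP predictive variance includes the fitted noise variance, so far
  from data it reverts to signal-plus-noise — the scale on which LCB
  exploration is calibrated.
* Campaign feature reduction (global-Shapley threshold, default 0.05) is
  off until two augmentation rounds have passed and only fires when more
  than ten features remain; dropped features are held at mid-bounds in
  subsequent suggestions, as a lab would fix de-selected excipients at a
  reference composition.
* The campaign stops at cross-validated $R^2 \ge 0.9$ by default —
  screening-model territory where further optimization rarely pays — or
  when the budget is exhausted.
* Response-zone extraction defaults to the 20th percentile of the grid
  (type-1 quantile, so the cell count tracks the percentile up to ties);
  published zones are usually chosen visually, so the threshold is exposed.

### Problem sizes used by the test-suite simulations

Module tests run at n of tens to a few hundred rows; the end-to-end checks
use 200-observation screens (100 formulations in duplicate), 40 + 40
observation campaigns with batches of 5, and 10-seed replicate loops.
These sizes were chosen to match the scale of the emulated screening
studies while keeping the full suite a desk-scale run.

## Known limitations

* Attribution-based feature selection has a detectability floor: effects
  whose contribution is small relative to assay noise at screening sample
  sizes (on the default landscape, the starting-titer covariate and the
  spiked-albumin effect, whose knee at 2 mg/mL leaves most of its 0–15
  mg/mL range flat) attribute at the same magnitude as the spurious
  dependence a depth-20 ensemble learns on null features. No threshold
  separates such features reliably; recovering them requires either more
  data or a stronger prior than a screening campaign has. The package's
  own acceptance checks document this honestly rather than masking it.
* The GP is isotropic by default; strongly anisotropic surfaces are
  modeled only through the shared length-scale.
* Exact Shapley is exponential in the feature count; beyond 14 features
  only the sampled estimator is available.
* Tree surrogates cannot extrapolate beyond the convex hull of training
  data; response maps evaluated at unexplored corners reflect nearest
  training data, not the model "knowing" the corner.

## A short worked example

```{r example, eval = FALSE}
library(formbo)

land <- titer_landscape()                         # synthetic ground truth
init <- generate_dataset(land, n = 40, replicates = 1, seed = 1)

cfg <- campaign_config(budget = 40, batch_size = 5, seed = 1,
                       feature_reduction = list(enabled = FALSE))
log <- run_campaign(init, land$oracle, cfg)
log$step_table                                    # data size, model, RMSE ± sd, R²

min(dataset_response(log$dataset))                # best observed loss
land$true_minimum                                 # analytic optimum: 0.3

map <- grid_predict(log$final_model, land$space,
                    "residual_rHSA", "spiked_rHSA")
extract_zone(map)                                 # low-loss operating zone
```
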