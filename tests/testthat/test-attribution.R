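lin3_model <- function(a = c(2, -1, 0), n = 25, seed = 3) {
  X <- withr::with_seed(seed, data.frame(f1 = runif(n), f2 = runif(n), f3 = runif(n)))
  y <- drop(as.matrix(X) %*% a) + 0.5
  fit_model(linear_model_spec(), X, y, seed = 1)
}

test_that("exact Shapley on additive models equals the closed form a_i (x_i - mean bg)", {
  a <- c(2, -1, 0)
  fm <- lin3_model(a)
  bg <- withr::with_seed(8, data.frame(f1 = runif(30), f2 = runif(30), f3 = runif(30)))
  inst <- c(f1 = 0.9, f2 = 0.1, f3 = 0.5)
  ex <- shap_exact(fm, inst, bg)
  closed <- a * (inst - colMeans(bg))
  expect_equal(unname(ex$phi), unname(closed), tolerance = 1e-8)
  expect_equal(ex$phi[["f3"]], 0)                        # zero-coefficient feature
  expect_equal(sum(ex$phi) + ex$base_value, ex$prediction, tolerance = 1e-6)
})

test_that("exact Shapley matches the permutation-enumeration oracle on small models", {
  bg <- withr::with_seed(4, data.frame(f1 = runif(12), f2 = runif(12), f3 = runif(12)))
  y <- withr::with_seed(5, rnorm(12))
  # a genuinely non-additive model: a small tree ensemble
  tree <- fit_model(tree_ensemble_spec(n_estimators = 5, max_depth = 3), bg, y, seed = 2)
  lin <- lin3_model()
  for (model in list(tree, lin)) {
    inst <- withr::with_seed(6, setNames(runif(3), c("f1", "f2", "f3")))
    ex <- shap_exact(model, inst, bg)
    oracle <- bruteforce_shap(model, inst, bg)
    expect_equal(ex$phi, oracle, tolerance = 1e-8)
  }
})

test_that("Shapley symmetry: interchangeable features receive equal attribution", {
  X <- withr::with_seed(2, data.frame(f1 = runif(20), f2 = runif(20)))
  fm <- fit_model(oracle_model_spec(function(df) df$f1 + df$f2), X, rep(0, 20))
  bg <- data.frame(f1 = c(0.2, 0.7, 0.4), f2 = c(0.2, 0.7, 0.4))
  ex <- shap_exact(fm, c(f1 = 0.9, f2 = 0.9), bg)
  expect_equal(ex$phi[["f1"]], ex$phi[["f2"]], tolerance = 1e-6)
})

test_that("sampled Shapley is seeded, efficient for any permutation count, and converges", {
  fm <- lin3_model(c(1.5, -2, 0.7))
  bg <- withr::with_seed(9, data.frame(f1 = runif(20), f2 = runif(20), f3 = runif(20)))
  inst <- c(f1 = 0.8, f2 = 0.3, f3 = 0.6)
  s1 <- shap_sampled(fm, inst, bg, n_permutations = 1, seed = 3)
  expect_equal(sum(s1$phi) + s1$base_value, s1$prediction, tolerance = 1e-10)
  s2a <- shap_sampled(fm, inst, bg, n_permutations = 25, seed = 7)
  s2b <- shap_sampled(fm, inst, bg, n_permutations = 25, seed = 7)
  expect_identical(s2a$phi, s2b$phi)
  ex <- shap_exact(fm, inst, bg)
  s3 <- shap_sampled(fm, inst, bg, n_permutations = 2000, seed = 1)
  expect_lt(max(abs(s3$phi - ex$phi)), 0.05 * max(abs(ex$phi)))
})

test_that("global ranking puts the only informative feature first and ignores duplicates", {
  X <- withr::with_seed(3, data.frame(f1 = runif(15), f2 = runif(15), f3 = runif(15)))
  fm <- fit_model(oracle_model_spec(function(df) 3 * df$f1), X, rep(0, 15))
  gs <- global_shap(fm, X, mode = "exact")
  expect_equal(gs$ranking$feature[1], "f1")
  expect_equal(gs$ranking$mean_abs_phi[2:3], c(0, 0))
  # duplicated rows leave the ranking unchanged
  gs2 <- global_shap(fm, rbind(X, X), background = X, mode = "exact")
  expect_equal(gs2$ranking, gs$ranking)
})

test_that("dependence data reveal monotone and saturating effects", {
  sp <- design_space(feature_spec("c_sat", 0, 5), feature_spec("c_lin", 0, 5))
  X <- sample_design(sp, 60, scheme = "latin", seed = 12)
  knee <- 2
  fm <- fit_model(oracle_model_spec(function(df) {
    0.4 * pmin(df$c_sat, knee) / knee + 0.2 * df$c_lin
  }), X, rep(0, 60))
  dep_lin <- shap_dependence(fm, X, "c_lin", mode = "exact")
  expect_gte(cor(dep_lin$value, dep_lin$phi, method = "spearman"), 0.8)
  dep_sat <- shap_dependence(fm, X, "c_sat", mode = "exact")
  below <- dep_sat$phi[dep_sat$value < knee]
  above <- dep_sat$phi[dep_sat$value > knee]
  expect_gt(mean(above), mean(below))      # saturated side carries higher phi
  expect_lt(diff(range(above)), 0.2 * diff(range(dep_sat$phi)))  # flat plateau
})

test_that("select_features keeps everything under equal importance and only the top as the threshold grows", {
  r_equal <- structure(list(ranking = data.frame(
    feature = c("a", "b", "c"), mean_abs_phi = c(1, 1, 1))),
    class = "global_shap_ranking")
  expect_equal(select_features(r_equal, 0.05), c("a", "b", "c"))
  r_mix <- structure(list(ranking = data.frame(
    feature = c("a", "b", "c"), mean_abs_phi = c(1, 0.5, 0.01))),
    class = "global_shap_ranking")
  expect_equal(select_features(r_mix, 0.999), "a")
  expect_equal(select_features(r_mix, 0.05), c("a", "b"))
  expect_error(select_features(r_mix, 0), class = "formbo_config_error")
})

test_that("wrapper elimination isolates strong features and tolerates nulls", {
  # compact landscape: one dominant, one moderate, one null feature
  sp <- design_space(feature_spec("strong", 0, 10), feature_spec("weak", 0, 10),
                     feature_spec("null", 0, 10))
  hits <- 0; null_ok <- 0
  n_rep <- 6
  for (s in seq_len(n_rep)) {
    X <- sample_design(sp, 120, scheme = "latin", seed = 700 + s)
    y <- 0.1 * X$strong + 0.03 * pmin(X$weak, 5) +
      withr::with_seed(s, rnorm(120, 0, 0.08))
    ds <- formulation_dataset(sp, cbind(X, resp = y), "resp")
    wr <- wrapper_elimination(tree_ensemble_spec(), ds, k = 5, seed = s)
    hits <- hits + (wr$rows$group[1] == "strong")
    null_ok <- null_ok + (abs(wr$rows$delta_r2[wr$rows$group == "null"]) <= 0.05)
  }
  expect_gte(hits, n_rep - 1)
  expect_gte(null_ok, n_rep - 1)
})

test_that("wrapper group removal equals joint removal of its members", {
  ds <- small_dataset(n = 30, noise_sd = 0.05)
  spec <- feature_spec("total_rHSA", 0, 6.5, "mg/mL", role = "derived",
                       parents = c("residual_rHSA", "spiked_rHSA"))
  ds3 <- add_derived_feature(ds, spec)
  wr <- wrapper_elimination(
    linear_model_spec(), ds3,
    groups = list(parents = c("residual_rHSA", "spiked_rHSA"),
                  res = "residual_rHSA"),
    k = 5, seed = 2)
  # removing the pair is exactly CV on the remaining (total) column
  direct <- kfold_cv(linear_model_spec(), ds3, features = "total_rHSA",
                     k = 5, seed = 2)
  expect_equal(wr$rows$r2[wr$rows$group == "parents"], direct$r2, tolerance = 1e-12)
  expect_error(
    wrapper_elimination(linear_model_spec(), ds,
                        groups = list(all = c("residual_rHSA", "spiked_rHSA"))),
    class = "formbo_config_error")
  expect_error(
    wrapper_elimination(linear_model_spec(), ds, groups = list(bad = character())),
    class = "formbo_config_error")
})

test_that("permutation importance is exactly zero for unread features and seeded", {
  X <- withr::with_seed(1, data.frame(f1 = runif(40), f2 = runif(40)))
  y <- 2 * X$f1 + withr::with_seed(2, rnorm(40, 0, 0.1))
  fm <- fit_model(oracle_model_spec(function(df) 2 * df$f1), X, y)
  pi1 <- permutation_importance(fm, X, y, n_repeats = 5, seed = 3)
  expect_equal(pi1$rows$mean_increase[pi1$rows$feature == "f2"], 0)
  expect_gt(pi1$rows$mean_increase[pi1$rows$feature == "f1"], 0.1)
  pi2 <- permutation_importance(fm, X, y, n_repeats = 5, seed = 3)
  expect_identical(pi1$rows, pi2$rows)
})

test_that("wrapper, permutation and Shapley rankings agree on a dominant effect", {
  sp <- design_space(feature_spec("dom", 0, 10), feature_spec("mid", 0, 10),
                     feature_spec("null", 0, 10))
  agree <- 0
  n_rep <- 5
  for (s in seq_len(n_rep)) {
    X <- sample_design(sp, 100, scheme = "latin", seed = 900 + s)
    y <- 0.12 * X$dom + 0.02 * X$mid + withr::with_seed(s, rnorm(100, 0, 0.08))
    ds <- formulation_dataset(sp, cbind(X, resp = y), "resp")
    fm <- fit_model(tree_ensemble_spec(), X, y, seed = s)
    gs <- global_shap(fm, X[1:40, ], background = X, mode = "exact")
    wr <- wrapper_elimination(tree_ensemble_spec(), ds, k = 5, seed = s)
    pi <- permutation_importance(fm, X, y, n_repeats = 5, seed = s)
    tops <- c(gs$ranking$feature[1], wr$rows$group[1], pi$rows$feature[1])
    agree <- agree + all(tops == "dom")
  }
  expect_gte(agree, n_rep - 1)
})

test_that("exact mode refuses too many features and points to sampling", {
  M <- 16
  X <- as.data.frame(matrix(runif(2 * M), 2, M))
  fm <- fit_model(linear_model_spec(), X, c(0, 1))
  expect_error(shap_exact(fm, X[1, ], X), class = "formbo_config_error")
})
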