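test_that("lcb implements mu - kappa * sigma with domain checks", {
  expect_equal(lcb(1.0, 0.25, 2), 0.0)
  expect_equal(lcb(c(1, 2), c(0, 1), 0), c(1, 2))       # kappa = 0 -> mean
  ks <- c(0, 0.5, 1, 2, 8)
  vals <- vapply(ks, function(k) lcb(1, 0.09, k), numeric(1))
  expect_true(all(diff(vals) < 0))                       # non-increasing in kappa
  expect_error(lcb(1, 0.1, -1), class = "formbo_config_error")
  expect_error(lcb(1, -0.1, 1), class = "formbo_domain_error")
})

test_that("strategy presets map onto kappa and custom requires kappa", {
  expect_equal(acquisition_config("exploitation")$kappa, 0.1)
  expect_equal(acquisition_config("balanced")$kappa, 1.96)
  expect_equal(acquisition_config("exploration")$kappa, 8.0)
  expect_equal(acquisition_config("custom", kappa = 3.3)$kappa, 3.3)
  expect_error(acquisition_config("custom"), class = "formbo_config_error")
})

test_that("candidate pools are seeded, in bounds and respect constraints", {
  sp <- rhsa_space(constraints = list(linear_constraint(
    c(residual_rHSA = 1, spiked_rHSA = 1), 4)))
  p1 <- candidate_pool(sp, 200, seed = 7)
  p2 <- candidate_pool(sp, 200, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1$residual_rHSA >= 0 & p1$residual_rHSA <= 1.5))
  expect_true(all(p1$residual_rHSA + p1$spiked_rHSA <= 4 + 1e-9))
})

test_that("singleton selection matches exhaustive pool scoring", {
  ds <- small_dataset(n = 15)
  sc <- scale_to_unit(ds)
  gp <- fit_gp(sc$X, dataset_response(ds), seed = 2)
  for (kap in c(0, 1.96, 8)) {
    cfg <- acquisition_config("custom", kappa = kap, batch_size = 1,
                              pool_size = 512, polish = FALSE, seed = 11)
    sb <- suggest_batch(gp, ds$space, cfg)
    pool <- candidate_pool(ds$space, 512, seed = 11)
    U <- scale_to_unit(as.matrix(pool), space = ds$space)$X
    p <- predict_gp(gp, U)
    acq <- lcb(p$mean, p$var, kap)
    expect_equal(sb$acquisition_values, min(acq), tolerance = 1e-12)
    expect_equal(unlist(sb$candidates), unlist(pool[which.min(acq), ]),
                 tolerance = 1e-12)
  }
})

test_that("exploration suggests where a dense grid says uncertainty is highest", {
  sp <- design_space(feature_spec("x", 0, 1))
  X <- matrix(c(0.2, 0.8), ncol = 1, dimnames = list(NULL, "x"))
  gp <- fit_gp(X, c(1, 1.2), noise_var = 0, seed = 1)
  cfg <- acquisition_config("exploration", batch_size = 1, pool_size = 1024, seed = 3)
  sb <- suggest_batch(gp, sp, cfg)
  grid <- matrix(seq(0, 1, length.out = 2001), ncol = 1)
  sd_grid <- sqrt(predict_gp(gp, grid)$var)
  top_region <- grid[sd_grid >= max(sd_grid) - 1e-6, 1]
  x_star <- sb$candidates$x[1]
  expect_lt(min(abs(x_star - top_region)), 0.02)
})

test_that("batches contain distinct in-bounds candidates and are seed-reproducible", {
  ds <- small_dataset(n = 15)
  sc <- scale_to_unit(ds)
  gp <- fit_gp(sc$X, dataset_response(ds), seed = 2)
  cfg <- acquisition_config("balanced", batch_size = 3, pool_size = 256, seed = 5)
  sb <- suggest_batch(gp, ds$space, cfg)
  expect_equal(nrow(sb$candidates), 3L)
  expect_equal(nrow(unique(sb$candidates)), 3L)
  b <- as.data.frame(ds$space)
  for (i in seq_along(b$name)) {
    expect_true(all(sb$candidates[[b$name[i]]] >= b$lower[i] - 1e-9))
    expect_true(all(sb$candidates[[b$name[i]]] <= b$upper[i] + 1e-9))
  }
  sb2 <- suggest_batch(gp, ds$space, cfg)
  expect_identical(sb$candidates, sb2$candidates)
})

test_that("with kappa = 0 the suggestion exploits at least as well as training data", {
  ds <- small_dataset(n = 20)
  sc <- scale_to_unit(ds)
  gp <- fit_gp(sc$X, dataset_response(ds), noise_var = 0, seed = 2)
  cfg <- acquisition_config("custom", kappa = 0, batch_size = 1,
                            pool_size = 1024, seed = 9)
  sb <- suggest_batch(gp, ds$space, cfg)
  # predicted mean at the suggestion is no worse than the best observation
  U <- scale_to_unit(as.matrix(sb$candidates), space = ds$space)$X
  expect_lte(predict_gp(gp, U)$mean, min(dataset_response(ds)) + 0.05)
})

test_that("increasing kappa weakly increases the suggestion's posterior sd", {
  sp <- design_space(feature_spec("x", 0, 1))
  X <- matrix(c(0.1, 0.35, 0.55, 0.9), ncol = 1, dimnames = list(NULL, "x"))
  gp <- fit_gp(X, c(0.9, 0.4, 0.6, 1.3), noise_var = 0, seed = 1)
  sds <- vapply(c(0, 1, 4, 16), function(kap) {
    cfg <- acquisition_config("custom", kappa = kap, batch_size = 1,
                              pool_size = 512, seed = 4)
    sb <- suggest_batch(gp, sp, cfg)
    U <- scale_to_unit(as.matrix(sb$candidates), space = sp)$X
    sqrt(predict_gp(gp, U)$var)
  }, numeric(1))
  expect_true(all(diff(sds) >= -1e-8))
})

test_that("infeasible constraints raise a feasibility error", {
  sp <- rhsa_space(constraints = list(linear_constraint(
    c(residual_rHSA = 1), -1)))    # residual <= -1: impossible
  expect_error(candidate_pool(sp, 50, seed = 1), class = "formbo_feasibility_error")
})

test_that("suggestions can be written as CSV with acquisition values", {
  ds <- small_dataset(n = 12)
  sc <- scale_to_unit(ds)
  gp <- fit_gp(sc$X, dataset_response(ds), seed = 2)
  sb <- suggest_batch(gp, ds$space,
                      acquisition_config(batch_size = 2, pool_size = 128, seed = 1))
  f <- tempfile(fileext = ".csv")
  write_suggestions(sb, f)
  out <- read.csv(f)
  expect_equal(nrow(out), 2L)
  expect_true("acquisition" %in% names(out))
})
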