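test_that("titer truth reproduces its construction at reference points", {
  p <- titer_landscape_params()
  ref <- data.frame(residual_rHSA = 0, spiked_rHSA = 0,
                    excipient_A = 0, excipient_B = 0, excipient_C = 0,
                    excipient_E = 0, excipient_I = 0, excipient_D = p$quadratic_feature$optimum,
                    starting_titer = p$starting_titer_range[1])
  expect_equal(titer_loss_truth(p, ref), p$baseline_loss)
  # full residual effect between 0 and the knee, exact plateau beyond it
  at_knee <- ref; at_knee$residual_rHSA <- p$residual_knee
  past_knee <- ref; past_knee$residual_rHSA <- 2 * p$residual_knee
  expect_equal(titer_loss_truth(p, ref) - titer_loss_truth(p, at_knee),
               p$residual_effect)
  expect_equal(titer_loss_truth(p, at_knee), titer_loss_truth(p, past_knee))
  expect_error(titer_loss_truth(p, ref[, -1]), class = "formbo_schema_error")
})

test_that("titer truth is monotone in both albumin features and flat past the knees", {
  L <- titer_landscape()
  base <- sample_design(L$space, 40, scheme = "latin", seed = 5)
  res_grid <- seq(0, 1.5, length.out = 31)
  sp_grid <- seq(0, 15, length.out = 31)
  for (r in 1:5) {
    row <- base[r, ]
    f_res <- vapply(res_grid, function(v) {
      row$residual_rHSA <- v; titer_loss_truth(L$params, row)
    }, numeric(1))
    expect_true(all(diff(f_res) <= 1e-12))      # protective: non-increasing
    expect_equal(diff(range(f_res[res_grid >= L$params$residual_knee])), 0)
    f_sp <- vapply(sp_grid, function(v) {
      row$spiked_rHSA <- v; titer_loss_truth(L$params, row)
    }, numeric(1))
    expect_true(all(diff(f_sp) >= -1e-12))      # destabilizing: non-decreasing
    expect_equal(diff(range(f_sp[sp_grid >= L$params$spiked_knee])), 0)
  }
})

test_that("the landscape's stated optimum matches a dense search", {
  L <- titer_landscape()
  cand <- sample_design(L$space, 4000, scheme = "uniform", seed = 8)
  expect_gte(min(titer_loss_truth(L$params, cand)), L$true_minimum)
  expect_equal(titer_loss_truth(L$params, L$true_argmin), L$true_minimum)
})

test_that("Fox mixture rule: single-component and equal-Tg identities, frozen binary value", {
  p <- tg_mixture_params()
  comps <- p$components$name
  zero <- as.data.frame(as.list(setNames(rep(0, length(comps)), comps)))
  pure_pvp <- zero; pure_pvp$pvp <- 50
  expect_equal(tg_truth(p, pure_pvp), -26)
  # two components sharing a Tg: any blend returns that Tg (sorbitol/arginine, -44)
  blend <- zero; blend$sorbitol <- 13; blend$arginine <- 29
  expect_equal(tg_truth(p, blend), -44, tolerance = 1e-12)
  # frozen regression value: equal-mass binary of -26 and -44 components
  bin <- zero; bin$pvp <- 10; bin$sorbitol <- 10
  expect_equal(tg_truth(p, bin), -35.3401217719924, tolerance = 1e-10)
  expect_error(tg_truth(p, zero), class = "formbo_domain_error")
})

test_that("Fox rule is monotone when mass shifts toward the higher-Tg component", {
  p <- tg_mixture_params()
  comps <- p$components$name
  zero <- as.data.frame(as.list(setNames(rep(0, length(comps)), comps)))
  tgs <- vapply(seq(0, 20, by = 2), function(w) {
    f <- zero; f$pvp <- w; f$proline <- 20 - w + 1e-9
    tg_truth(p, f)
  }, numeric(1))
  expect_true(all(diff(tgs) > 0))
})

test_that("designs are seeded, in bounds, and latin sampling stratifies each dimension", {
  sp <- rhsa_space()
  d1 <- sample_design(sp, 10, scheme = "latin", seed = 3)
  d2 <- sample_design(sp, 10, scheme = "latin", seed = 3)
  expect_identical(d1, d2)
  u <- scale_to_unit(as.matrix(d1), space = sp)$X
  for (j in 1:2) {
    expect_equal(sort(unique(floor(u[, j] * 10))), 0:9)   # one sample per decile
  }
  d3 <- sample_design(sp, 25, scheme = "uniform", seed = 4)
  expect_true(all(d3$spiked_rHSA >= 0 & d3$spiked_rHSA <= 5))
})

test_that("generated datasets carry replicate structure and calibrated noise", {
  L <- titer_landscape()
  ds0 <- generate_dataset(L, n = 8, replicates = 2, seed = 2)
  expect_equal(n_observations(ds0), 16L)
  expect_equal(unique(ds0$data$source_tag), "synthetic")
  expect_equal(sort(unique(ds0$data$replicate_id)), c(1L, 2L))
  # noiseless oracle: duplicates are identical
  Lq <- titer_landscape(titer_landscape_params(noise_sd = 0))
  dsq <- generate_dataset(Lq, n = 6, replicates = 2, seed = 2)
  y <- dataset_response(dsq)
  expect_equal(y[seq(1, 11, 2)], y[seq(2, 12, 2)])
  # noise sd within chi-square-style bounds at n = 200 x 2
  ds <- generate_dataset(L, n = 200, replicates = 2, seed = 9)
  resid <- dataset_response(ds) - attr(ds, "truth")
  expect_gt(sd(resid), 0.085)
  expect_lt(sd(resid), 0.115)
})

test_that("averaging duplicates beats single replicates in RMSE against truth", {
  L <- titer_landscape()
  ds <- generate_dataset(L, n = 150, replicates = 2, seed = 13)
  truth <- attr(ds, "truth")
  y <- dataset_response(ds)
  odd <- seq(1, length(y), 2)
  single_rmse <- rmse(truth[odd], y[odd])
  avg <- (y[odd] + y[odd + 1]) / 2
  avg_rmse <- rmse(truth[odd], avg)
  expect_lt(avg_rmse, single_rmse)
})

test_that("oracle queries are reproducible given the seed", {
  L <- tg_landscape()
  f <- sample_design(L$space, 5, seed = 1)
  q1 <- query_oracle(L$oracle, f, replicates = 2, seed = 6)
  q2 <- query_oracle(L$oracle, f, replicates = 2, seed = 6)
  expect_identical(q1, q2)
  expect_equal(nrow(q1), 10L)
})
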