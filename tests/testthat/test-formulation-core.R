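test_that("feature and design-space validation rejects bad inputs", {
  expect_error(feature_spec("x", 1, 1), class = "formbo_config_error")
  expect_error(feature_spec("x", 0, Inf), class = "formbo_config_error")
  expect_error(feature_spec("t", 0, 1, role = "derived"), class = "formbo_config_error")
  expect_error(design_space(feature_spec("a", 0, 1), feature_spec("a", 0, 2)),
               class = "formbo_config_error")
  expect_error(
    design_space(feature_spec("a", 0, 1),
                 feature_spec("t", 0, 2, role = "derived", parents = "missing")),
    class = "formbo_config_error")
  expect_error(
    design_space(feature_spec("a", 0, 1),
                 constraints = list(linear_constraint(c(zz = 1), 1))),
    class = "formbo_config_error")
})

test_that("CSV round-trip is lossless and preserves row order", {
  sp <- rhsa_space()
  df <- data.frame(residual_rHSA = c(0.123456789012, 1.5, 0),
                   spiked_rHSA = c(4.987654321098, 0, 2.5),
                   loss = c(1.1, 0.2345678901234, 2))
  ds <- formulation_dataset(sp, df, "loss")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(ds, f1)
  ds2 <- load_dataset(f1, sp, "loss")
  write_dataset(ds2, f2)
  ds3 <- load_dataset(f2, sp, "loss")
  expect_equal(n_observations(ds3), 3L)
  expect_equal(dataset_features(ds3), dataset_features(ds), tolerance = 1e-12)
  expect_equal(dataset_response(ds3), dataset_response(ds), tolerance = 1e-12)
})

test_that("load_dataset flags schema problems and ignores unknown columns", {
  sp <- rhsa_space()
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(residual_rHSA = 1, spiked_rHSA = 2), f, row.names = FALSE)
  expect_error(load_dataset(f, sp, "loss"), class = "formbo_schema_error")
  write.csv(data.frame(residual_rHSA = 1, spiked_rHSA = 2, loss = 0.5,
                       operator = "x"), f, row.names = FALSE)
  expect_warning(ds <- load_dataset(f, sp, "loss"), "unknown")
  expect_equal(n_observations(ds), 1L)
  write.csv(data.frame(residual_rHSA = "oops", spiked_rHSA = 2, loss = 0.5),
            f, row.names = FALSE)
  expect_error(suppressWarnings(load_dataset(f, sp, "loss")),
               class = "formbo_parse_error")
})

test_that("derived feature columns are computed as parent sums", {
  sp <- rhsa_space_with_total()
  df <- data.frame(residual_rHSA = c(0.2, 1.2, 0.05, 1.0, 0.5),
                   spiked_rHSA = c(1.0, 0, 4.5, 2.2, 0.3),
                   loss = 1:5 / 10)
  ds <- formulation_dataset(sp, df, "loss")
  expect_equal(ds$data$total_rHSA, df$residual_rHSA + df$spiked_rHSA)
  # fixed residual 1.2, spiked sweep: totals track the sweep exactly
  sweep_df <- data.frame(residual_rHSA = 1.2,
                         spiked_rHSA = seq(0, 5, by = 0.5),
                         loss = 0)
  ds2 <- formulation_dataset(sp, sweep_df, "loss")
  expect_equal(ds2$data$total_rHSA, 1.2 + seq(0, 5, by = 0.5))
  expect_equal(range(ds2$data$total_rHSA), c(1.2, 6.2))
})

test_that("add_derived_feature appends a summed column and rejects collisions", {
  ds <- small_dataset()
  spec <- feature_spec("total_rHSA", 0, 6.5, "mg/mL", role = "derived",
                       parents = c("residual_rHSA", "spiked_rHSA"))
  ds2 <- add_derived_feature(ds, spec)
  expect_equal(ds2$data$total_rHSA,
               ds$data$residual_rHSA + ds$data$spiked_rHSA)
  expect_error(add_derived_feature(ds2, spec), class = "formbo_config_error")
  expect_error(add_derived_feature(ds, feature_spec("z", 0, 1)),
               class = "formbo_config_error")
})

test_that("unit scaling is affine, bijective and strict mode enforces bounds", {
  ds <- small_dataset(n = 20)
  sc <- scale_to_unit(ds)
  expect_true(all(sc$X >= 0 & sc$X <= 1))
  # round trip
  back <- sc$unscale(sc$X)
  expect_equal(back, dataset_features(ds), tolerance = 1e-12)
  # endpoints and midpoint of a [0, 5] column
  sp <- rhsa_space()
  M <- matrix(c(0, 0, 1.5, 5, 0.75, 2.5), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("residual_rHSA", "spiked_rHSA")))
  U <- scale_to_unit(M, space = sp)$X
  expect_equal(unname(U[1, ]), c(0, 0))
  expect_equal(unname(U[2, ]), c(1, 1))
  expect_equal(unname(U[3, "spiked_rHSA"]), 0.5)
  # monotone per column
  expect_true(all(diff(scale_to_unit(cbind(residual_rHSA = seq(0, 1.5, 0.1),
                                           spiked_rHSA = 1), space = sp)$X[, 1]) > 0))
  bad <- M; bad[1, 1] <- -0.5
  expect_error(scale_to_unit(bad, space = sp, strict = TRUE),
               class = "formbo_range_error")
})

test_that("out-of-bounds data warns by default and errors in strict mode", {
  sp <- rhsa_space()
  df <- data.frame(residual_rHSA = 2.5, spiked_rHSA = 1, loss = 1)
  expect_warning(formulation_dataset(sp, df, "loss"), "outside")
  expect_error(formulation_dataset(sp, df, "loss", validate = "strict"),
               class = "formbo_range_error")
})

test_that("design-space JSON round-trips features and constraints", {
  sp <- design_space(
    feature_spec("a", 0, 10, "mg/mL"),
    feature_spec("b", 0, 5, "% w/v", role = "covariate"),
    feature_spec("t", 0, 15, role = "derived", parents = c("a", "b")),
    constraints = list(linear_constraint(c(a = 1, b = 2), 12))
  )
  f <- tempfile(fileext = ".json")
  write_design_space(sp, f)
  sp2 <- read_design_space(f)
  expect_equal(as.data.frame(sp2), as.data.frame(sp))
  expect_equal(sp2$constraints[[1]]$coefficients, sp$constraints[[1]]$coefficients)
})
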