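sim_linear <- function(n, seed, sigma = 0.5) {
  set.seed(seed)
  X <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10))
  list(X = X, y = 2 * X$x1 + rnorm(n, 0, sigma))
}

test_that("AIC stepwise selection keeps the signal and drops the noise", {
  d <- sim_linear(200, seed = 30)
  expect_equal(select_variables(d$X, d$y, model_spec("MLR")), "x1")
  expect_equal(select_variables(d$X, d$y, model_spec("MLR", "backward")), "x1")

  # single candidate kept only when it beats the intercept-only AIC
  expect_equal(select_variables(d$X["x1"], d$y, model_spec("MLR")), "x1")
  set.seed(31)
  noise <- data.frame(z = rnorm(200))
  expect_length(select_variables(noise, d$y, model_spec("MLR")), 0)
})

test_that("AIC ties break towards the lexicographically smaller subset", {
  set.seed(32)
  a <- runif(100)
  X <- data.frame(b = a, a = a)  # identical columns, reversed column order
  y <- 3 * a + rnorm(100, 0, 0.1)
  expect_equal(select_variables(X, y, model_spec("MLR")), "a")
})

test_that("every family in the roster fits and satisfies the metric invariants", {
  set.seed(33)
  n <- 140
  X <- data.frame(x1 = runif(n, 0, 3000), x2 = runif(n))
  y <- plogis(-1 + 0.0006 * X$x1 + 0.5 * X$x2 + rnorm(n, 0, 0.3))
  for (spec in default_model_specs()) {
    row <- crossvalidate(spec, X, y, folds = 5, repeats = 2, seed = 1)
    expect_false(row$failed, label = spec$family)
    expect_equal(row$rmse_test^2, row$mse_test, tolerance = 1e-8,
                 label = spec$family)
    expect_equal(row$rmse_train^2, row$mse_train, tolerance = 1e-8,
                 label = spec$family)
    expect_gte(row$aicc_train, row$aic_train)
    expect_gte(row$aicc_test, row$aic_test)
    expect_true(is.finite(row$r2_test), label = spec$family)
  }
})

test_that("cross-validation is exact for an oracle predictor and honest for none", {
  set.seed(34)
  y <- rnorm(80)
  row <- crossvalidate(model_spec("MLR"), data.frame(x = y), y,
                       folds = 5, repeats = 3, seed = 2)
  expect_lt(row$mae_test, 1e-10)
  expect_equal(row$r2_test, 1, tolerance = 1e-10)

  row0 <- crossvalidate(model_spec("MLR"), data.frame(y)[, 0, drop = FALSE], y,
                        folds = 5, repeats = 3, seed = 2)
  expect_lt(row0$r2_test, 0)  # out-of-sample R2 of the intercept-only model
})

test_that("MLR held-out RMSE tracks the known noise level", {
  rmse <- vapply(1:20, function(s) {
    d <- sim_linear(500, seed = 100 + s, sigma = 0.5)
    crossvalidate(model_spec("MLR"), d$X["x1"], d$y, folds = 10,
                  repeats = 1, seed = s)$rmse_test
  }, 0)
  expect_equal(mean(rmse), 0.5, tolerance = 0.05)
})

test_that("cross-validation is reproducible for a fixed seed", {
  d <- sim_linear(120, seed = 35)
  r1 <- crossvalidate(model_spec("RT"), d$X, d$y, folds = 5, repeats = 3, seed = 9)
  r2 <- crossvalidate(model_spec("RT"), d$X, d$y, folds = 5, repeats = 3, seed = 9)
  expect_identical(r1, r2)
  r3 <- crossvalidate(model_spec("RT"), d$X, d$y, folds = 5, repeats = 3, seed = 10)
  expect_false(identical(r1$r2_test, r3$r2_test))
})

test_that("compare_models returns identical rows for duplicate specs and picks a best", {
  d <- sim_linear(150, seed = 36)
  cmp <- compare_models(list(model_spec("MLR"), model_spec("MLR"),
                             model_spec("RT")),
                        d$X, d$y, folds = 5, repeats = 2, seed = 3,
                        select = FALSE)
  expect_equal(cmp$report[1, ], cmp$report[2, ], ignore_attr = TRUE)
  expect_true(cmp$best %in% c("MLR", "RT"))
  # linear truth: MLR should win on test R2
  expect_equal(cmp$best, "MLR")
})

test_that("a family that cannot fit is recorded as a failed row, not an error", {
  set.seed(37)
  X <- data.frame(x = runif(80))
  y <- -5 + 2 * X$x + rnorm(80)  # negative response: beta regression must fail
  cmp <- compare_models(list(model_spec("MLR"), model_spec("BR")),
                        X, y, folds = 5, repeats = 1, seed = 1, select = FALSE)
  expect_true(cmp$report$failed[cmp$report$family == "BR"])
  expect_false(cmp$report$failed[cmp$report$family == "MLR"])
  expect_equal(cmp$best, "MLR")
})
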