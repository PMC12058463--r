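sim_gam_data <- function(n, seed, f, sigma = 0.05) {
  set.seed(seed)
  X <- data.frame(elevation = runif(n, 54, 3070), tpi = rnorm(n, 0, 200))
  list(X = X, y = f(X$elevation, X$tpi) + rnorm(n, 0, sigma))
}

test_that("fixed-df smoothers report exactly the requested df", {
  d <- sim_gam_data(136, seed = 40, f = function(e, t) 0.5 - 1e-4 * e + 1e-4 * t)
  fit <- fit_gam(d$y, c(elevation = 4, tpi = 4), d$X)
  edf <- gam_term_edf(fit)
  expect_equal(unname(edf["elevation"]), 4, tolerance = 0.1)
  expect_equal(unname(edf["tpi"]), 4, tolerance = 0.1)
  expect_error(fit_gam(d$y, c(elevation = 4), d$X[integer(0), , drop = FALSE]),
               class = "fdg_value_error")
  expect_error(fit_gam(rep(1, 5), c(x = 4),
                       data.frame(x = c(1, 1, 2, 2, 3))),
               class = "fdg_value_error")  # df >= distinct values
})

test_that("partial effects are centred and sum with the intercept to the fitted values", {
  d <- sim_gam_data(136, seed = 41,
                    f = function(e, t) 0.4 + 0.1 * sin(e / 500) + 2e-4 * t)
  fit <- fit_gam(d$y, c(elevation = 4, tpi = 4), d$X)
  tm <- stats::predict(fit$model, type = "terms")
  expect_equal(fit$intercept + rowSums(tm), fit$fitted, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(colMeans(tm)), c(0, 0), tolerance = 1e-10)
  # stored curves carry positive standard errors over the training range
  expect_true(all(fit$partial$elevation$se > 0))
  expect_equal(range(fit$partial$elevation$x), range(d$X$elevation))
})

test_that("a linear signal yields a flat nonparametric test and a strong parametric one", {
  hits_np <- logical(50); hits_par <- logical(50)
  for (s in 1:50) {
    d <- sim_gam_data(150, seed = 400 + s,
                      f = function(e, t) 2e-4 * e, sigma = 0.1)
    fit <- fit_gam(d$y, c(elevation = 4), d$X["elevation"])
    an <- gam_anova(fit)
    hits_np[s] <- an$nonparametric$p[1] > 0.05
    hits_par[s] <- an$parametric$p[1] < 1e-4
  }
  expect_gte(mean(hits_np), 0.9)
  expect_gte(mean(hits_par), 0.99)
})

test_that("a hump-shaped effect is located to within 150 m of its true optimum", {
  argmaxes <- vapply(1:20, function(s) {
    d <- sim_gam_data(300, seed = 500 + s,
                      f = function(e, t) -((e - 1500) / 1500)^2, sigma = 0.1)
    fit <- fit_gam(d$y, c(elevation = 4), d$X["elevation"])
    pe <- fit$partial$elevation
    pe$x[which.max(pe$effect)]
  }, 0)
  expect_true(all(abs(argmaxes - 1500) <= 150))
})

test_that("pure-noise responses rarely produce significant terms", {
  np_ok <- logical(100); par_ok <- logical(100)
  for (s in 1:100) {
    set.seed(600 + s)
    X <- data.frame(elevation = runif(100, 0, 3000))
    y <- rnorm(100)
    an <- gam_anova(fit_gam(y, c(elevation = 4), X))
    np_ok[s] <- an$nonparametric$p[1] > 0.05
    par_ok[s] <- an$parametric$p[1] > 0.05
  }
  expect_gte(mean(np_ok), 0.9)
  expect_gte(mean(par_ok), 0.9)
})

test_that("the ANOVA table mirrors the two-block layout with the right df", {
  d <- sim_gam_data(136, seed = 42,
                    f = function(e, t) 0.5 - 1e-4 * e + 1e-4 * t, sigma = 0.03)
  fit <- fit_gam(d$y, c(elevation = 4, tpi = 4), d$X)
  an <- gam_anova(fit)
  expect_equal(nrow(an$parametric), 3)           # two terms + residuals
  expect_equal(an$parametric$df, c(1, 1, 136 - 1 - 8))
  expect_equal(an$nonparametric$npar_df, c(3, 3))
  expect_equal(an$df_residual, 127)
  expect_equal(an$parametric$sum_sq[3] / an$parametric$df[3],
               an$parametric$mean_sq[3])
})

test_that("grid prediction matches fitted values in-sample and flags extrapolation", {
  d <- sim_gam_data(120, seed = 43,
                    f = function(e, t) 0.4 - 1e-4 * e + 1e-4 * t)
  fit <- fit_gam(d$y, c(elevation = 4, tpi = 4), d$X)
  out <- predict_grid(fit, d$X)
  expect_equal(out$prediction, fit$fitted, tolerance = 1e-10)
  expect_false(any(out$extrapolated))
  expect_equal(nrow(out), nrow(d$X))

  grid <- data.frame(elevation = c(10, 1500, 5000), tpi = c(0, 0, 0),
                     x = 1:3, y = 1:3)
  out2 <- predict_grid(fit, grid)
  expect_equal(out2$extrapolated, c(TRUE, FALSE, TRUE))
  # clamped prediction equals the range-edge prediction
  edge <- predict_grid(fit, data.frame(elevation = max(d$X$elevation), tpi = 0))
  expect_equal(out2$prediction[3], edge$prediction, tolerance = 1e-10)
  expect_error(predict_grid(fit, data.frame(elevation = 1:3)),
               class = "fdg_value_error")
})
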