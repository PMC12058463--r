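# Final-model GAM: additive cubic regression splines at fixed target degrees
# of freedom (e.g. FD ~ s(elevation, df = 4) + s(TPI, df = 4)), the two-block
# ANOVA table (parametric effects / nonparametric effects), mean-centred
# partial-effect curves with pointwise standard-error bands, and prediction
# over an environment grid with range clamping.

#' Fit an additive model with fixed-df smoothers
#'
#' Each term is a cubic regression spline constrained to exactly the requested
#' equivalent degrees of freedom (unpenalised basis of df + 1 functions with
#' the usual centring constraint), so a df = 4 smooth consumes 4 model df.
#'
#' @param y Numeric response.
#' @param terms Named numeric vector of target df per covariate, e.g.
#'   `c(elevation = 4, tpi = 4)`.
#' @param X Data.frame holding the covariates.
#' @param n_grid Grid length for the stored partial-effect curves.
#' @return A `gam_fit`: the mgcv model plus `terms`, `intercept`, training
#'   ranges, fitted values and `partial` (per-term data.frame with the
#'   covariate grid, centred effect and standard error).
#' @export
fit_gam <- function(y, terms, X, n_grid = 200) {
  terms <- unlist(terms)
  terms <- stats::setNames(as.integer(round(terms)), names(terms))
  fdg_assert(!is.null(names(terms)) && all(names(terms) %in% names(X)),
             "terms must be a named df vector matching columns of X",
             "fdg_value_error")
  fdg_assert(all(terms >= 1), "target df must be >= 1", "fdg_value_error")
  for (v in names(terms)) {
    nu <- length(unique(X[[v]]))
    fdg_assert(terms[[v]] < nu,
               sprintf("df for '%s' must be below its %d distinct values", v, nu),
               "fdg_value_error")
    fdg_assert(all(is.finite(X[[v]])), sprintf("non-finite values in '%s'", v),
               "fdg_value_error")
  }
  rhs <- vapply(names(terms), function(v) {
    if (terms[[v]] == 1) v
    else sprintf("s(%s, k = %d, fx = TRUE, bs = 'cr')", v, terms[[v]] + 1)
  }, "")
  d <- cbind(.y = y, X[, names(terms), drop = FALSE])
  form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  model <- mgcv::gam(form, data = d, method = "REML")

  ranges <- lapply(X[, names(terms), drop = FALSE], range)
  partial <- lapply(names(terms), function(v) {
    grid <- data.frame(seq(ranges[[v]][1], ranges[[v]][2], length.out = n_grid))
    names(grid) <- v
    for (other in setdiff(names(terms), v)) {
      grid[[other]] <- stats::median(X[[other]])
    }
    pr <- stats::predict(model, newdata = grid, type = "terms", se.fit = TRUE)
    col <- grep(paste0("\\b", v, "\\b"), colnames(pr$fit))
    data.frame(x = grid[[v]], effect = pr$fit[, col[1]],
               se = pr$se.fit[, col[1]])
  })
  names(partial) <- names(terms)

  structure(list(model = model, terms = terms, y = y,
                 X = X[, names(terms), drop = FALSE],
                 intercept = unname(stats::coef(model)[1]),
                 fitted = unname(stats::fitted(model)),
                 edf = sum(smooth_edf(model)), ranges = ranges,
                 partial = partial),
            class = "gam_fit")
}

smooth_edf <- function(model) {
  # per-smooth edf; fixed-df smooths report exactly their target df
  if (length(model$smooth) == 0) return(numeric(0))
  vapply(model$smooth, function(s) sum(model$edf[s$first.para:s$last.para]), 0)
}

#' Per-term effective degrees of freedom of a `gam_fit`
#' @param fit A [fit_gam()] result.
#' @return Named numeric vector of per-term edf.
#' @export
gam_term_edf <- function(fit) {
  sm <- smooth_edf(fit$model)
  names(sm) <- vapply(fit$model$smooth, function(s) s$term, "")
  out <- fit$terms * NA_real_
  for (v in names(fit$terms)) {
    out[v] <- if (v %in% names(sm)) sm[[v]] else 1
  }
  out
}

#' Two-block ANOVA table for a fixed-df GAM
#'
#' The parametric block tests the linear part of each term: sequential
#' least-squares sums of squares referred to the full GAM's residual mean
#' square on F(1, df_res). The nonparametric block tests each smooth against
#' its linear restriction: F = ((RSS_linear - RSS_full)/(df - 1)) / MS_res on
#' F(df - 1, df_res), where df is the smooth's target df.
#'
#' @param fit A [fit_gam()] result.
#' @return List with data.frames `parametric` (term, df, sum_sq, mean_sq, f,
#'   p; final row = residuals) and `nonparametric` (term, npar_df, f, p).
#' @export
gam_anova <- function(fit) {
  y <- fit$y
  X <- fit$X
  n <- length(y)
  df_res <- n - 1 - sum(fit$terms)
  rss_full <- sum((y - fit$fitted)^2)
  ms_res <- rss_full / df_res

  lin <- stats::lm(y ~ ., data = X[, names(fit$terms), drop = FALSE])
  seq_ss <- stats::anova(lin)
  par_rows <- do.call(rbind, lapply(names(fit$terms), function(v) {
    ss <- seq_ss[v, "Sum Sq"]
    f <- (ss / 1) / ms_res
    data.frame(term = sprintf("s(%s, df = %d)", v, fit$terms[[v]]),
               df = 1, sum_sq = ss, mean_sq = ss,
               f = f, p = stats::pf(f, 1, df_res, lower.tail = FALSE))
  }))
  par_rows <- rbind(par_rows,
                    data.frame(term = "Residuals", df = df_res,
                               sum_sq = rss_full, mean_sq = ms_res,
                               f = NA_real_, p = NA_real_))

  npar_rows <- do.call(rbind, lapply(names(fit$terms), function(v) {
    dfv <- fit$terms[[v]]
    if (dfv <= 1) {
      return(data.frame(term = v, npar_df = 0, f = NA_real_, p = NA_real_))
    }
    reduced_terms <- fit$terms
    reduced_terms[v] <- 1
    red <- fit_gam(y, reduced_terms, X)
    rss_red <- sum((y - red$fitted)^2)
    f <- ((rss_red - rss_full) / (dfv - 1)) / ms_res
    data.frame(term = sprintf("s(%s, df = %d)", v, dfv),
               npar_df = dfv - 1, f = f,
               p = stats::pf(f, dfv - 1, df_res, lower.tail = FALSE))
  }))
  list(parametric = par_rows, nonparametric = npar_rows,
       df_residual = df_res, rss = rss_full)
}

#' Predict a fitted GAM over an environment grid
#'
#' Covariate values outside the training range are clamped to the range edges
#' and flagged as extrapolated.
#'
#' @param fit A [fit_gam()] result.
#' @param grid Data.frame supplying every model covariate (extra columns such
#'   as coordinates are carried through).
#' @return `grid` plus columns `prediction` and `extrapolated`.
#' @export
predict_grid <- function(fit, grid) {
  missing <- setdiff(names(fit$terms), names(grid))
  fdg_assert(length(missing) == 0,
             sprintf("grid lacks model covariates: %s",
                     paste(missing, collapse = ", ")),
             "fdg_value_error")
  clamped <- grid
  flag <- rep(FALSE, nrow(grid))
  for (v in names(fit$terms)) {
    r <- fit$ranges[[v]]
    out <- grid[[v]] < r[1] | grid[[v]] > r[2]
    flag <- flag | out
    clamped[[v]] <- pmin(pmax(grid[[v]], r[1]), r[2])
  }
  grid$prediction <- as.numeric(stats::predict(fit$model, newdata = clamped))
  grid$extrapolated <- flag
  grid
}
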