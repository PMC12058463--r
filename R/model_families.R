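# The eleven-family regression roster used by the model-comparison harness:
# multiple linear regression (MLR), partial least squares (PLSR), ridge (RR),
# regression tree (RT), multivariate adaptive regression splines (MARS),
# generalized additive model (GAM), beta regression (BR), quantile regression
# at tau = 0.5 and 0.75 (QR50/QR75), Huber regression, and MM-estimation.
#
# Each family is wrapped behind a single fit interface returning the fitted
# values, a prediction closure, and an effective parameter count k used by the
# information criteria. For least-squares-like families
#   AIC  = n log(RSS/n) + 2 (k + 1)
#   AICc = AIC + 2 (k + 1)(k + 2) / (n - k - 2)
# (the +1 counts the error variance). Quantile regression uses the check-loss
# analogue n log(mean rho_tau) + 2(k + 1); beta regression uses its exact
# likelihood.

MODEL_FAMILIES <- c("MLR", "PLSR", "RR", "RT", "MARS", "GAM", "BR",
                    "QR50", "QR75", "HUBER", "MM")

#' Specify a regression family for the comparison harness
#'
#' @param family One of `"MLR"`, `"PLSR"`, `"RR"`, `"RT"`, `"MARS"`, `"GAM"`,
#'   `"BR"`, `"QR50"`, `"QR75"`, `"HUBER"`, `"MM"`.
#' @param selection Variable-selection direction, `"stepwise"` (greedy
#'   forward with drop steps) or `"backward"`.
#' @param ... Family hyperparameters (e.g. `ncomp_max` for PLSR,
#'   `lambda_grid` for RR, `max_terms` for MARS, `k_basis` for GAM).
#' @return A `model_spec` list.
#' @export
model_spec <- function(family, selection = c("stepwise", "backward"), ...) {
  family <- match.arg(family, MODEL_FAMILIES)
  selection <- match.arg(selection)
  structure(list(family = family, selection = selection, opts = list(...)),
            class = "model_spec")
}

#' Fit one regression family
#'
#' @param spec A [model_spec()].
#' @param X Data.frame of numeric covariates (may have zero columns for the
#'   intercept-only model).
#' @param y Numeric response.
#' @return An `fdg_fit` list: `fitted`, `predict(newdata)`, `k` (effective
#'   parameters including the intercept), `rss`, `aic`, `aicc`, plus
#'   family-specific pieces.
#' @export
fit_family <- function(spec, X, y) {
  fdg_assert(is.data.frame(X) && nrow(X) == length(y) || ncol(X) == 0,
             "X must be a data.frame aligned with y", "fdg_value_error")
  n <- length(y)
  if (ncol(X) == 0) {
    fit <- fit_intercept_only(spec, y)
  } else {
    fit <- switch(spec$family,
      MLR = fit_lm(X, y),
      PLSR = fit_pls(X, y, spec$opts),
      RR = fit_ridge(X, y, spec$opts),
      RT = fit_tree(X, y, spec$opts),
      MARS = fit_mars(X, y, spec$opts),
      GAM = fit_gam_family(X, y, spec$opts),
      BR = fit_beta(X, y),
      QR50 = fit_quantile(X, y, tau = 0.5),
      QR75 = fit_quantile(X, y, tau = 0.75),
      HUBER = fit_rlm(X, y, mm = FALSE),
      MM = fit_rlm(X, y, mm = TRUE)
    )
  }
  fit$spec <- spec
  fit$n <- n
  fit$vars <- names(X)
  crit <- information_criteria(spec, y, fit$fitted, fit$k, extra = fit)
  fit$rss <- sum((y - fit$fitted)^2)
  fit$aic <- crit$aic
  fit$aicc <- crit$aicc
  class(fit) <- "fdg_fit"
  fit
}

#' @export
predict.fdg_fit <- function(object, newdata, ...) object$predict(newdata)

fit_intercept_only <- function(spec, y) {
  mu <- if (spec$family == "QR50") stats::quantile(y, 0.5, names = FALSE)
        else if (spec$family == "QR75") stats::quantile(y, 0.75, names = FALSE)
        else mean(y)
  list(fitted = rep(mu, length(y)),
       predict = function(newdata) rep(mu, nrow(newdata)), k = 1)
}

fit_lm <- function(X, y) {
  d <- cbind(.y = y, X)
  m <- stats::lm(.y ~ ., data = d)
  list(fitted = unname(stats::fitted(m)),
       predict = function(newdata) unname(stats::predict(m, newdata)),
       k = length(stats::coef(m)), model = m)
}

# PLS1 via NIPALS; the number of components is chosen by a deterministic
# internal 5-fold CV over 1..min(10, p, n-2).
fit_pls <- function(X, y, opts) {
  Xm <- as.matrix(X)
  n <- nrow(Xm); p <- ncol(Xm)
  ncomp_max <- min(opts$ncomp_max %||% 10L, p, n - 2L)
  fold <- ((seq_len(n) - 1L) %% 5L) + 1L
  cv_err <- rep(Inf, ncomp_max)
  for (nc in seq_len(ncomp_max)) {
    sse <- 0
    for (f in 1:5) {
      tr <- fold != f
      if (sum(tr) <= nc + 1) { sse <- Inf; break }
      b <- nipals_pls(Xm[tr, , drop = FALSE], y[tr], nc)
      pred <- drop(sweep(Xm[!tr, , drop = FALSE], 2, b$mx) %*% b$beta) + b$my
      sse <- sse + sum((y[!tr] - pred)^2)
    }
    cv_err[nc] <- sse
  }
  ncomp <- which.min(cv_err)
  b <- nipals_pls(Xm, y, ncomp)
  pred_fn <- function(newdata) {
    drop(sweep(as.matrix(newdata[, colnames(Xm), drop = FALSE]), 2, b$mx) %*%
           b$beta) + b$my
  }
  list(fitted = pred_fn(X), predict = pred_fn, k = ncomp + 1, ncomp = ncomp)
}

nipals_pls <- function(X, y, ncomp) {
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx); yc <- y - my
  p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]; q <- q[seq_len(a - 1)]; break }
    w <- w / nw
    t_sc <- drop(Xc %*% w)
    tt <- sum(t_sc^2)
    pl <- drop(crossprod(Xc, t_sc)) / tt
    qa <- sum(yc * t_sc) / tt
    Xc <- Xc - tcrossprod(t_sc, pl)
    yc <- yc - qa * t_sc
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
  }
  beta <- W %*% solve(crossprod(P, W), q)
  list(beta = drop(beta), mx = mx, my = my)
}

fit_ridge <- function(X, y, opts) {
  lambda <- opts$lambda_grid %||% seq(0, 20, by = 0.1)
  d <- cbind(.y = y, X)
  m <- MASS::lm.ridge(.y ~ ., data = d, lambda = lambda)
  best <- which.min(m$GCV)
  cf <- stats::coef(m)
  cf <- if (is.matrix(cf)) cf[best, ] else cf
  sv <- svd(scale(as.matrix(X), center = TRUE, scale = TRUE))$d
  edf <- sum(sv^2 / (sv^2 + lambda[best])) + 1
  pred_fn <- function(newdata) {
    drop(as.matrix(cbind(1, newdata[, names(X), drop = FALSE])) %*% cf)
  }
  list(fitted = pred_fn(X), predict = pred_fn, k = edf,
       lambda = lambda[best])
}

fit_tree <- function(X, y, opts) {
  d <- cbind(.y = y, X)
  m <- rpart::rpart(.y ~ ., data = d, method = "anova",
                    control = rpart::rpart.control(
                      cp = opts$cp %||% 0.01, minsplit = opts$minsplit %||% 10))
  list(fitted = unname(stats::predict(m, d)),
       predict = function(newdata) unname(stats::predict(m, newdata)),
       k = sum(m$frame$var == "<leaf>"), model = m)
}

# Degree-1 MARS: greedy forward selection of reflected hinge pairs at
# quantile knots, then backward pruning by the usual GCV criterion with
# penalty 3 effective parameters per knot.
fit_mars <- function(X, y, opts) {
  Xm <- as.matrix(X)
  n <- nrow(Xm)
  max_terms <- opts$max_terms %||% min(21L, 2L * ncol(Xm) * 3L + 1L, n - 2L)
  knots_per_var <- opts$knots %||% 11L
  ls_fit <- function(B) {
    q <- qr(B)
    cf <- qr.coef(q, y)
    cf[is.na(cf)] <- 0
    list(coef = cf, rss = sum((y - drop(B %*% cf))^2), rank = q$rank)
  }
  basis <- list(function(M) rep(1, nrow(M)))
  B <- matrix(1, n, 1)
  repeat {
    if (ncol(B) + 2 > max_terms) break
    best <- NULL; best_rss <- ls_fit(B)$rss
    improved <- FALSE
    for (j in seq_len(ncol(Xm))) {
      kn <- unique(stats::quantile(Xm[, j],
              probs = seq(0.1, 0.9, length.out = knots_per_var), names = FALSE))
      for (t0 in kn) {
        h1 <- pmax(Xm[, j] - t0, 0); h2 <- pmax(t0 - Xm[, j], 0)
        Bc <- cbind(B, h1, h2)
        fit <- ls_fit(Bc)
        if (fit$rank < ncol(Bc)) next  # degenerate hinge pair: no new information
        if (fit$rss < best_rss - 1e-12) {
          best_rss <- fit$rss; best <- list(j = j, t0 = t0); improved <- TRUE
        }
      }
    }
    if (!improved) break
    j <- best$j; t0 <- best$t0
    local({
      jj <- j; tt <- t0
      basis[[length(basis) + 1]] <<- function(M) pmax(M[, jj] - tt, 0)
      basis[[length(basis) + 1]] <<- function(M) pmax(tt - M[, jj], 0)
    })
    B <- cbind(B, pmax(Xm[, j] - t0, 0), pmax(t0 - Xm[, j], 0))
  }
  # backward pruning by GCV
  keep <- seq_len(ncol(B))
  gcv <- function(idx) {
    rss <- ls_fit(B[, idx, drop = FALSE])$rss
    M <- length(idx); C <- M + 3 * (M - 1) / 2
    if (C >= n) return(Inf)
    (rss / n) / (1 - C / n)^2
  }
  best_gcv <- gcv(keep)
  repeat {
    if (length(keep) <= 1) break
    cand <- lapply(keep[-1], function(drop_i) setdiff(keep, drop_i))
    g <- vapply(cand, gcv, 0)
    if (min(g) < best_gcv) {
      best_gcv <- min(g); keep <- cand[[which.min(g)]]
    } else break
  }
  cf <- ls_fit(B[, keep, drop = FALSE])$coef
  basis_keep <- basis[keep]
  vars <- colnames(Xm)
  pred_fn <- function(newdata) {
    M <- as.matrix(newdata[, vars, drop = FALSE])
    Bn <- vapply(basis_keep, function(f) f(M), numeric(nrow(M)))
    if (is.null(dim(Bn))) Bn <- matrix(Bn, nrow = 1)
    drop(Bn %*% cf)
  }
  list(fitted = pred_fn(X), predict = pred_fn, k = length(keep),
       n_terms = length(keep))
}

fit_gam_family <- function(X, y, opts) {
  k_basis <- opts$k_basis %||% 10L
  terms <- vapply(names(X), function(v) {
    nu <- length(unique(X[[v]]))
    if (nu >= 4) sprintf("s(%s, k = %d, bs = 'cr')", v, min(k_basis, nu - 1))
    else v
  }, "")
  d <- cbind(.y = y, X)
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  m <- mgcv::gam(form, data = d, method = "REML")
  list(fitted = unname(stats::fitted(m)),
       predict = function(newdata) unname(stats::predict(m, newdata)),
       k = sum(m$edf) + 1, model = m)
}

# Beta regression needs y in the open unit interval; when the response
# touches 0 or 1 the standard squeeze (y (n-1) + 0.5)/n is applied.
fit_beta <- function(X, y) {
  n <- length(y)
  squeezed <- any(y <= 0 | y >= 1)
  y2 <- if (squeezed) (y * (n - 1) + 0.5) / n else y
  d <- cbind(.y = y2, X)
  form <- stats::as.formula(paste(".y ~", paste(names(X), collapse = " + ")))
  m <- glmmTMB::glmmTMB(form, data = d, family = glmmTMB::beta_family())
  ll <- stats::logLik(m)
  list(fitted = unname(stats::predict(m, type = "response")),
       predict = function(newdata) {
         nd <- newdata[, names(X), drop = FALSE]
         nd$.y <- 0.5
         unname(stats::predict(m, newdata = nd, type = "response",
                               allow.new.levels = TRUE))
       },
       k = attr(ll, "df"), loglik = as.numeric(ll), squeezed = squeezed,
       model = m)
}

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# Quantile regression by iteratively reweighted least squares on the check
# loss (Schlossmacher-type weights), started from the LS fit.
fit_quantile <- function(X, y, tau, maxit = 100, tol = 1e-9) {
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  beta <- stats::lsfit(Xm, y, intercept = FALSE)$coefficients
  eps <- 1e-6
  loss_old <- Inf
  for (it in seq_len(maxit)) {
    r <- y - drop(Xm %*% beta)
    w <- abs(tau - (r < 0)) / pmax(abs(r), eps)
    beta <- stats::lsfit(Xm, y, wt = w, intercept = FALSE)$coefficients
    loss <- check_loss(y - drop(Xm %*% beta), tau)
    if (abs(loss_old - loss) < tol * (abs(loss_old) + tol)) break
    loss_old <- loss
  }
  vars <- colnames(as.matrix(X))
  pred_fn <- function(newdata) {
    drop(cbind(1, as.matrix(newdata[, vars, drop = FALSE])) %*% beta)
  }
  list(fitted = pred_fn(X), predict = pred_fn, k = length(beta), tau = tau)
}

fit_rlm <- function(X, y, mm) {
  d <- cbind(.y = y, X)
  m <- if (mm) MASS::rlm(.y ~ ., data = d, method = "MM", maxit = 200)
       else MASS::rlm(.y ~ ., data = d, psi = MASS::psi.huber, maxit = 200)
  list(fitted = unname(stats::fitted(m)),
       predict = function(newdata) unname(stats::predict(m, newdata)),
       k = length(stats::coef(m)), model = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Information criteria on (possibly held-out) residuals. k includes the
# intercept; the error scale adds one further parameter.
information_criteria <- function(spec, y, yhat, k, extra = NULL) {
  n <- length(y)
  if (spec$family %in% c("QR50", "QR75")) {
    tau <- if (spec$family == "QR50") 0.5 else 0.75
    loss <- check_loss(y - yhat, tau) / n
    aic <- n * log(max(loss, 1e-300)) + 2 * (k + 1)
  } else if (spec$family == "BR" && !is.null(extra$loglik)) {
    aic <- -2 * extra$loglik + 2 * k
  } else {
    rss <- sum((y - yhat)^2)
    aic <- n * log(max(rss / n, 1e-300)) + 2 * (k + 1)
  }
  denom <- n - k - 2
  aicc <- if (denom > 0) aic + 2 * (k + 1) * (k + 2) / denom else Inf
  list(aic = aic, aicc = aicc)
}

# Harness metrics for a prediction vector. R2 is 1 - SSE/SST (so an
# uninformative model scores <= 0 out of sample); quantile families report the
# check-loss pseudo-R2 against the intercept-only quantile instead.
prediction_metrics <- function(spec, y, yhat) {
  mae <- mean(abs(y - yhat))
  mse <- mean((y - yhat)^2)
  if (spec$family %in% c("QR50", "QR75")) {
    tau <- if (spec$family == "QR50") 0.5 else 0.75
    l0 <- check_loss(y - stats::quantile(y, tau, names = FALSE), tau)
    r2 <- 1 - check_loss(y - yhat, tau) / l0
  } else {
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) NA_real_ else 1 - sum((y - yhat)^2) / sst
  }
  list(r2 = r2, mae = mae, mse = mse, rmse = sqrt(mse))
}
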