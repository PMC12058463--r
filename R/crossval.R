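# AIC-based variable selection and the repeated 10-fold cross-validation
# harness comparing the regression families.

#' Greedy AIC-based variable selection
#'
#' Stepwise (forward with drop steps) or backward search minimising the
#' family's AIC. Deterministic: candidate moves are evaluated in column order
#' and AIC ties are broken in favour of the lexicographically smaller variable
#' subset.
#'
#' @param X Data.frame of candidate covariates.
#' @param y Numeric response (`length(y) > ncol(X)`).
#' @param spec A [model_spec()]; its `selection` field sets the direction.
#' @param tol Minimum AIC improvement to accept a move.
#' @return Character vector of selected covariate names (possibly empty).
#' @export
select_variables <- function(X, y, spec = model_spec("MLR"), tol = 1e-8) {
  fdg_assert(length(y) > ncol(X),
             "need more observations than candidate covariates",
             "fdg_value_error")
  score <- function(vars) {
    fit_family(spec, X[, vars, drop = FALSE], y)$aic
  }
  subset_key <- function(vars) paste(sort(vars), collapse = "\r")
  all_vars <- names(X)
  current <- if (spec$selection == "backward") all_vars else character(0)
  current_aic <- score(current)
  repeat {
    moves <- list()
    if (spec$selection %in% c("stepwise", "backward")) {
      for (v in current) moves[[length(moves) + 1]] <- setdiff(current, v)
    }
    if (spec$selection == "stepwise") {
      for (v in setdiff(all_vars, current)) {
        moves[[length(moves) + 1]] <- c(current, v)
      }
    }
    if (length(moves) == 0) break
    aics <- vapply(moves, function(vs) {
      tryCatch(score(vs), error = function(e) Inf)
    }, 0)
    best <- min(aics)
    if (best < current_aic - tol) {
      cand <- moves[abs(aics - best) < tol]
      keys <- vapply(cand, subset_key, "")
      current <- cand[[order(keys)[1]]]
      current_aic <- best
    } else if (abs(best - current_aic) <= tol) {
      # a tie with the incumbent: prefer the lexicographically smaller subset
      cand <- c(list(current), moves[abs(aics - best) < tol])
      keys <- vapply(cand, subset_key, "")
      chosen <- cand[[order(keys)[1]]]
      if (identical(sort(chosen), sort(current))) break
      current <- chosen; current_aic <- best
    } else break
  }
  fdg_assert(is.finite(current_aic), "no admissible model", "fdg_value_error")
  sort(current)
}

#' Repeated k-fold cross-validation of one family
#'
#' Per repeat, plots are randomly partitioned into `folds` folds; held-out
#' predictions are pooled within the repeat, metrics computed on the pool, and
#' then averaged over repeats. Training metrics and information criteria come
#' from the full-data fit; test information criteria use the same k with the
#' pooled held-out residuals.
#'
#' @inheritParams select_variables
#' @param folds Number of folds (default 10).
#' @param repeats Number of random re-partitions (default 100).
#' @param seed Integer seed controlling the fold draws.
#' @return One-row data.frame (a model-report row) with training/test R2,
#'   MAE, MSE, RMSE, AIC, AICc, the selected variables, and the CV settings.
#' @export
crossvalidate <- function(spec, X, y, folds = 10, repeats = 100, seed = 1) {
  n <- length(y)
  fdg_assert(n >= 2 * folds, "every fold needs at least 2 observations",
             "fdg_value_error")
  full <- fit_family(spec, X, y)
  tr_met <- prediction_metrics(spec, y, full$fitted)

  test_acc <- matrix(NA_real_, repeats, 6,
                     dimnames = list(NULL, c("r2", "mae", "mse", "rmse",
                                             "aic", "aicc")))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(folds), n))
    pred <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- fit_family(spec, X[tr, , drop = FALSE], y[tr])
      pred[!tr] <- fit$predict(X[!tr, , drop = FALSE])
    }
    met <- prediction_metrics(spec, y, pred)
    crit <- information_criteria(spec, y, pred, full$k,
                                 extra = if (spec$family == "BR")
                                   list(loglik = NULL) else NULL)
    test_acc[r, ] <- c(met$r2, met$mae, met$mse, met$rmse, crit$aic, crit$aicc)
  }
  te <- colMeans(test_acc)
  te["rmse"] <- sqrt(te["mse"])  # so RMSE^2 = MSE holds after averaging
  data.frame(
    family = spec$family,
    selected = paste(names(X), collapse = "+"),
    r2_train = tr_met$r2, mae_train = tr_met$mae, mse_train = tr_met$mse,
    rmse_train = tr_met$rmse, aic_train = full$aic, aicc_train = full$aicc,
    r2_test = te["r2"], mae_test = te["mae"], mse_test = te["mse"],
    rmse_test = te["rmse"], aic_test = te["aic"], aicc_test = te["aicc"],
    folds = folds, repeats = repeats, seed = seed, failed = FALSE,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Compare regression families by repeated cross-validation
#'
#' Runs optional AIC-based variable selection per family, then
#' [crossvalidate()], and picks the best family: highest test R2, ties broken
#' by the lower test AICc. A family that fails to fit is recorded as a failed
#' row rather than aborting the comparison.
#'
#' @param specs List of [model_spec()]s (>= 2).
#' @inheritParams crossvalidate
#' @param select Run [select_variables()] per family first.
#' @return List with `report` (one row per family) and `best` (family name).
#' @export
compare_models <- function(specs, X, y, folds = 10, repeats = 100, seed = 1,
                           select = TRUE) {
  fdg_assert(length(specs) >= 2, "need at least two model specs",
             "fdg_value_error")
  rows <- lapply(specs, function(spec) {
    tryCatch({
      Xs <- X
      if (select) {
        vars <- select_variables(X, y, spec)
        Xs <- X[, vars, drop = FALSE]
      }
      crossvalidate(spec, Xs, y, folds = folds, repeats = repeats, seed = seed)
    }, error = function(e) {
      data.frame(family = spec$family, selected = NA_character_,
                 r2_train = NA_real_, mae_train = NA_real_, mse_train = NA_real_,
                 rmse_train = NA_real_, aic_train = NA_real_, aicc_train = NA_real_,
                 r2_test = NA_real_, mae_test = NA_real_, mse_test = NA_real_,
                 rmse_test = NA_real_, aic_test = NA_real_, aicc_test = NA_real_,
                 folds = folds, repeats = repeats, seed = seed, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
  })
  report <- do.call(rbind, rows)
  ok <- report[!report$failed, , drop = FALSE]
  fdg_assert(nrow(ok) > 0, "every family failed to fit", "fdg_value_error")
  best_r2 <- max(ok$r2_test)
  tied <- ok[ok$r2_test >= best_r2 - 1e-8, , drop = FALSE]
  best <- tied$family[which.min(tied$aicc_test)]
  list(report = report, best = best)
}

#' The full eleven-family roster
#'
#' @param selection Selection direction passed to every [model_spec()].
#' @return List of specs covering MLR, PLSR, RR, RT, MARS, GAM, BR, QR50,
#'   QR75, HUBER and MM.
#' @export
default_model_specs <- function(selection = "stepwise") {
  lapply(MODEL_FAMILIES, model_spec, selection = selection)
}
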