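# Stratification of plots into Mediterranean vegetation belts (500-m elevation
# bands) and topographic position index groups, plus the descriptive
# statistics run on the strata (Pearson correlation, one-way ANOVA with post
# hoc pairwise comparisons, min-max scaled metric summaries).

BELT_LEVELS <- c("Thermo", "Meso", "Supra", "Oro", "Cryoro")

#' Classify elevation into Mediterranean vegetation belts
#'
#' Half-open 500-m bands, lower-inclusive: \[0,500) Thermo, \[500,1000) Meso,
#' \[1000,1500) Supra, \[1500,2000) Oro, \[2000,Inf) Cryoro.
#'
#' @param elevation Numeric vector of elevations in metres (>= 0).
#' @return Ordered factor with levels Thermo < Meso < Supra < Oro < Cryoro.
#' @export
classify_belt <- function(elevation) {
  fdg_assert(is.numeric(elevation) && !anyNA(elevation) && all(elevation >= 0),
             "elevation must be non-negative and non-missing", "fdg_value_error")
  cut(elevation, breaks = c(0, 500, 1000, 1500, 2000, Inf),
      labels = BELT_LEVELS, right = FALSE, ordered_result = TRUE)
}

#' Classify TPI values into topographic position groups
#'
#' Five groups partitioning the real line at the belt-mean-derived cutpoints,
#' half-open on the right: (-Inf,-377\] = 1, (-377,-198\] = 2, (-198,-32\] = 3,
#' (-32,146\] = 4, (146,Inf) = 5. The half-open convention closes the unit
#' gaps that integer-printed bounds (-376, -197, -31, +147) would leave on a
#' continuous scale.
#'
#' @param tpi Numeric vector of topographic position index values.
#' @return Integer vector of group codes 1-5.
#' @export
classify_tpi_group <- function(tpi) {
  fdg_assert(is.numeric(tpi) && all(is.finite(tpi)),
             "tpi must be finite", "fdg_value_error")
  as.integer(cut(tpi, breaks = c(-Inf, -377, -198, -32, 146, Inf),
                 right = TRUE))
}

#' Pearson correlation with two-sided test
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite, non-constant).
#' @return List with `r`, `p` (two-sided, from the t transform) and `n`.
#' @export
pearson <- function(x, y) {
  fdg_assert(length(x) == length(y) && length(x) >= 3,
             "need equal-length vectors with n >= 3", "fdg_value_error")
  fdg_assert(all(is.finite(x)) && all(is.finite(y)),
             "non-finite values in correlation input", "fdg_value_error")
  fdg_assert(stats::sd(x) > 0 && stats::sd(y) > 0,
             "zero variance: correlation undefined", "fdg_value_error")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way ANOVA with post hoc pairwise comparisons
#'
#' Tukey HSD by default; Games-Howell (Welch pairwise t with studentized-range
#' adjustment) as the unequal-variance alternative. Degenerate input in which
#' every observation is identical returns F = 0, p = 1 (no evidence of group
#' structure) rather than 0/0.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @param method `"tukey"` or `"games-howell"`.
#' @param conf_level Confidence level for the pairwise intervals.
#' @return List with `f`, `p`, `df`, `pairwise` (data.frame: pair, mean
#'   difference, adjusted p), and `group_stats` (n, mean, median, sd per group).
#' @export
anova_posthoc <- function(values, groups, method = c("tukey", "games-howell"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  groups <- factor(groups)
  groups <- droplevels(groups)
  fdg_assert(nlevels(groups) >= 2, "need at least two groups", "fdg_value_error")
  sizes <- table(groups)
  fdg_assert(all(sizes >= 2),
             sprintf("singleton group(s): %s",
                     paste(names(sizes)[sizes < 2], collapse = ", ")),
             "fdg_value_error")
  fdg_assert(length(values) == length(groups) && all(is.finite(values)),
             "values and groups must align and be finite", "fdg_value_error")

  group_stats <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               median = stats::median(v), sd = stats::sd(v))
  }))

  if (stats::var(values) == 0) {
    pairs <- utils::combn(levels(groups), 2)
    pairwise <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                           diff = 0, p_adj = 1)
    return(list(f = 0, p = 1, df = c(nlevels(groups) - 1,
                                     length(values) - nlevels(groups)),
                pairwise = pairwise, group_stats = group_stats,
                method = method))
  }

  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  f <- an[1, "F value"]; p <- an[1, "Pr(>F)"]
  df <- c(an[1, "Df"], an[2, "Df"])

  if (method == "tukey") {
    tk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
    pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                           p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    pairwise <- games_howell(values, groups)
  }
  list(f = f, p = p, df = df, pairwise = pairwise,
       group_stats = group_stats, method = method)
}

# Games-Howell: pairwise Welch t statistics referred to the studentized range
# distribution with Welch-Satterthwaite df; robust to unequal group variances.
games_howell <- function(values, groups) {
  lev <- levels(groups)
  k <- length(lev)
  stats_by <- lapply(lev, function(g) {
    v <- values[groups == g]
    list(n = length(v), m = mean(v), v = stats::var(v))
  })
  names(stats_by) <- lev
  out <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    a <- stats_by[[lev[i]]]; b <- stats_by[[lev[j]]]
    se2 <- a$v / a$n + b$v / b$n
    t_stat <- (b$m - a$m) / sqrt(se2)
    df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
    p <- stats::ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    out[[length(out) + 1]] <- data.frame(
      pair = paste(lev[j], lev[i], sep = "-"),
      diff = b$m - a$m, p_adj = p)
  }
  do.call(rbind, out)
}

#' Min-max scale the metric columns of a diversity table
#'
#' Maps each numeric metric column onto \[0,1\] across all plots (the min-max
#' transform), for comparable box plots across metrics. Constant columns map
#' to zeros.
#'
#' @param div A diversity table from [diversity_table()] (or any data.frame).
#' @param cols Columns to scale; defaults to the standard metric columns
#'   present.
#' @return The table with scaled metric columns.
#' @export
scale_metrics <- function(div, cols = intersect(
    c("fd_rao", "sd_shannon", "endemicity", "endemicity_w", "richness"),
    names(div))) {
  for (cn in cols) div[[cn]] <- minmax_standardize(div[[cn]])
  div
}
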