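# Mixed-type Gower dissimilarity between co-occurring species.
#
# d_jk = sum_i w_ijk * s_ijk / sum_i w_ijk over the eight traits, all equally
# weighted. Per-trait discordance s_ijk depends on the trait kind:
#   nominal  : 0 if the two category sets share a code, else 1 (multi-valued
#              sets extend the single-code equal/unequal rule; a Jaccard
#              alternative 1 - |A∩B|/|A∪B| is available but off by default)
#   interval : |x_j - x_k| / (max x - min x), range taken over the species
#              pool in scope (the plot pool by default)
#   ordinal  : |r_j - r_k| / (max r - min r), dense ranks over the distinct
#              values in scope
# The Boolean weight w_ijk drops traits that carry no information for a pair:
# w = 0 when the trait is missing in both species. When it is missing in only
# one species the classical Gower convention (default) also sets w = 0; the
# "mismatch" rule instead scores the pair as fully discordant (w = 1, s = 1),
# reading one-sided presence as information. A zero range (every species in
# scope shares one value) contributes s = 0: no information, no penalty.

#' Min-max standardization to \[0,1\]
#'
#' Maps the minimum to 0 and the maximum to 1; a constant vector maps to all
#' zeros (degenerate-range rule).
#'
#' @param x Numeric vector with at least one finite value.
#' @return Numeric vector in \[0,1\] (`NA`s propagate).
#' @export
minmax_standardize <- function(x) {
  fdg_assert(is.numeric(x) && any(is.finite(x)),
             "need at least one finite value", "fdg_value_error")
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) return(ifelse(is.na(x), NA_real_, 0))
  (x - rng[1]) / diff(rng)
}

#' Per-trait discordance between two species
#'
#' @param trait A [trait_definition()].
#' @param a,b Trait values: integer code vectors for nominal traits (length 0 =
#'   missing), scalars (`NA` = missing) for interval/ordinal traits.
#' @param pool_values For interval/ordinal traits, the trait's values over the
#'   species pool in scope (used for the range / dense ranks); ignored for
#'   nominal traits.
#' @param nominal_rule `"overlap"` (default; s = 0 iff the sets intersect) or
#'   `"jaccard"` (s = 1 - |A∩B|/|A∪B|).
#' @param missing_rule `"classical"` (one-sided missing drops the trait,
#'   w = 0) or `"mismatch"` (one-sided missing scores w = 1, s = 1).
#' @return List with elements `s` (discordance in \[0,1\], `NA` when w = 0)
#'   and `w` (0 or 1).
#' @export
trait_discordance <- function(trait, a, b, pool_values = NULL,
                              nominal_rule = c("overlap", "jaccard"),
                              missing_rule = c("classical", "mismatch")) {
  nominal_rule <- match.arg(nominal_rule)
  missing_rule <- match.arg(missing_rule)
  if (trait$kind == "nominal") {
    a <- as.integer(a[!is.na(a)]); b <- as.integer(b[!is.na(b)])
    ma <- length(a) == 0; mb <- length(b) == 0
    if (ma && mb) return(list(s = NA_real_, w = 0))
    if (ma || mb) {
      if (missing_rule == "classical") return(list(s = NA_real_, w = 0))
      return(list(s = 1, w = 1))
    }
    s <- if (nominal_rule == "overlap") {
      as.numeric(length(intersect(a, b)) == 0)
    } else {
      1 - length(intersect(a, b)) / length(union(a, b))
    }
    return(list(s = s, w = 1))
  }
  a <- as.numeric(a)[1]; b <- as.numeric(b)[1]
  if (is.na(a) && is.na(b)) return(list(s = NA_real_, w = 0))
  if (is.na(a) || is.na(b)) {
    if (missing_rule == "classical") return(list(s = NA_real_, w = 0))
    return(list(s = 1, w = 1))
  }
  vals <- pool_values[!is.na(pool_values)]
  fdg_assert(length(vals) > 0,
             "pool_values required for interval/ordinal traits",
             "fdg_value_error")
  if (trait$kind == "interval") {
    rng <- diff(range(vals))
    s <- if (rng == 0) 0 else abs(a - b) / rng
  } else {
    u <- sort(unique(vals))
    if (length(u) == 1) {
      s <- 0
    } else {
      s <- abs(match(a, u) - match(b, u)) / (length(u) - 1)
    }
  }
  list(s = s, w = 1)
}

#' Plot-level Gower dissimilarity matrix
#'
#' Computes the symmetric species-by-species dissimilarity matrix for one
#' plot's species pool over the eight mixed-type traits, all equally weighted.
#' Interval ranges and ordinal ranks are taken over the pool itself by default
#' (`range_scope = "plot"`), so dissimilarities are plot-contextual; set
#' `range_scope = "global"` to use the whole trait table instead.
#'
#' @param pool Character vector of species ids present in the plot.
#' @param traits A [trait_table()].
#' @inheritParams trait_discordance
#' @param range_scope `"plot"` or `"global"`.
#' @return Symmetric matrix with zero diagonal and entries in \[0,1\],
#'   dimnames = pool.
#' @export
gower_matrix <- function(pool, traits,
                         nominal_rule = c("overlap", "jaccard"),
                         missing_rule = c("classical", "mismatch"),
                         range_scope = c("plot", "global")) {
  nominal_rule <- match.arg(nominal_rule)
  missing_rule <- match.arg(missing_rule)
  range_scope <- match.arg(range_scope)
  pool <- as.character(pool)
  fdg_assert(length(pool) >= 1, "empty species pool", "fdg_value_error")
  idx <- match(pool, traits$species_id)
  fdg_assert(!anyNA(idx),
             sprintf("species not in trait table: %s",
                     paste(utils::head(pool[is.na(idx)], 5), collapse = ", ")),
             "fdg_value_error")
  schema <- attr(traits, "schema")
  m <- length(pool)
  S <- matrix(0, m, m); W <- matrix(0, m, m)

  for (tn in names(schema)) {
    def <- schema[[tn]]
    if (def$kind == "nominal") {
      sets <- traits[[tn]][idx]
      mask <- vapply(sets, function(v) sum(bitwShiftL(1L, v)), 0)
      pres <- mask > 0
      if (nominal_rule == "overlap") {
        s <- 1 - (outer(mask, mask, function(x, y) {
          mapply(bitwAnd, as.integer(x), as.integer(y))
        }) > 0)
      } else {
        n_and <- popcount_matrix(outer(mask, mask, function(x, y)
          mapply(bitwAnd, as.integer(x), as.integer(y))))
        n_or <- popcount_matrix(outer(mask, mask, function(x, y)
          mapply(bitwOr, as.integer(x), as.integer(y))))
        s <- ifelse(n_or > 0, 1 - n_and / n_or, 0)
      }
    } else {
      x <- traits[[tn]][idx]
      pres <- !is.na(x)
      scope_vals <- if (range_scope == "plot") x else traits[[tn]]
      scope_vals <- scope_vals[!is.na(scope_vals)]
      if (def$kind == "ordinal" && length(scope_vals) > 0) {
        u <- sort(unique(scope_vals))
        x <- as.numeric(match(x, u))
        rng <- length(u) - 1
      } else {
        rng <- if (length(scope_vals) > 0) diff(range(scope_vals)) else 0
      }
      x0 <- ifelse(pres, x, 0)
      s <- if (rng == 0) matrix(0, m, m) else abs(outer(x0, x0, "-")) / rng
    }
    both <- outer(pres, pres, "&")
    one <- xor(outer(pres, pres, "|"), both)
    w <- matrix(0, m, m)
    w[both] <- 1
    s[!both] <- 0
    if (missing_rule == "mismatch") {
      w[one] <- 1
      s[one] <- 1
    }
    S <- S + w * s
    W <- W + w
  }
  bad <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
  fdg_assert(nrow(bad) == 0,
             sprintf("no shared applicable trait for pair (%s, %s); cannot score dissimilarity",
                     pool[bad[1, 1]], pool[bad[1, 2]]),
             "fdg_value_error")
  d <- S / W
  diag(d) <- 0
  dimnames(d) <- list(pool, pool)
  d
}

popcount_matrix <- function(m) {
  matrix(vapply(as.integer(m), function(v) sum(bitwAnd(v, bitwShiftL(1L, 0:12)) > 0), 0),
         nrow(m), ncol(m))
}
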