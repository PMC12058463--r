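# Per-plot diversity metrics: Rao's quadratic entropy (functional diversity),
# Shannon-Wiener alpha diversity, endemicity, and first-order jackknife
# sampling adequacy.

#' Rao's quadratic entropy of one plot
#'
#' FD = sum_i sum_j p_i p_j d_ij over the full ordered double sum (both the
#' (i,j) and (j,i) pairs enter), with p the relative cover-code abundances.
#' Rao's Q generalises the Simpson index: when all inter-species
#' dissimilarities equal 1 it reduces to Gini-Simpson, 1 - sum p_i^2. Because
#' a functionally redundant species dilutes abundance without adding trait
#' distance, FD can fall while species richness rises.
#'
#' @param cover Named numeric vector of cover codes (>= 1) for the plot's
#'   present species.
#' @param D Square dissimilarity matrix from [gower_matrix()] whose dimnames
#'   match `names(cover)`.
#' @return Rao's Q (in \[0,1\] when `D` is).
#' @export
rao_q <- function(cover, D) {
  fdg_assert(is.numeric(cover) && all(cover >= 1),
             "cover codes must be >= 1 for present species", "fdg_value_error")
  fdg_assert(is.matrix(D) && nrow(D) == ncol(D) && nrow(D) == length(cover),
             "dissimilarity matrix does not match the plot's species",
             "fdg_value_error")
  if (!is.null(names(cover)) && !is.null(rownames(D))) {
    fdg_assert(setequal(names(cover), rownames(D)),
               "species ids of cover and D differ", "fdg_value_error")
    D <- D[names(cover), names(cover), drop = FALSE]
  }
  p <- cover / sum(cover)
  drop(t(p) %*% D %*% p)
}

#' Shannon-Wiener diversity of one plot
#'
#' H' = -sum p_i log p_i with 0 log 0 := 0; natural log by default.
#'
#' @inheritParams rao_q
#' @param base Logarithm base (e, 2 or 10).
#' @return H' (nats for the default base).
#' @export
shannon <- function(cover, base = exp(1)) {
  fdg_assert(is.numeric(cover) && length(cover) >= 1 && all(cover >= 1),
             "need at least one present species with cover >= 1",
             "fdg_value_error")
  p <- cover / sum(cover)
  -sum(p * log(p, base = base))
}

#' Per-plot endemicity
#'
#' Default: the fraction of the plot's species flagged endemic (richness
#' proportion). The abundance-weighted variant sums relative cover over the
#' endemic species instead.
#'
#' @param species Character vector of the plot's present species ids.
#' @param traits A [trait_table()] carrying the `endemic` flag.
#' @param cover Optional cover codes (needed for `weighted = TRUE`).
#' @param weighted Use the cover-weighted variant.
#' @return Endemicity in \[0,1\].
#' @export
endemicity <- function(species, traits, cover = NULL, weighted = FALSE) {
  idx <- match(as.character(species), traits$species_id)
  fdg_assert(!anyNA(idx), "species not in trait table", "fdg_value_error")
  flag <- traits$endemic[idx]
  if (!weighted) return(mean(flag))
  fdg_assert(!is.null(cover) && length(cover) == length(species),
             "cover required for weighted endemicity", "fdg_value_error")
  sum((cover / sum(cover))[flag])
}

#' First-order jackknife richness estimate
#'
#' S_jack = S_obs + Q1 (Q - 1) / Q, where Q is the number of plots and Q1 the
#' number of species occurring in exactly one plot.
#'
#' @param matrix An [abundance_matrix()] with at least two plots.
#' @return List with `s_obs`, `q`, `q1`, `s_jack` and
#'   `adequacy_ratio = s_obs / s_jack`.
#' @export
jackknife_richness <- function(matrix) {
  fdg_assert(nrow(matrix) >= 2,
             "jackknife estimator undefined for a single plot",
             "fdg_value_error")
  occ <- colSums(matrix > 0)
  s_obs <- sum(occ > 0)
  q <- nrow(matrix)
  q1 <- sum(occ == 1)
  s_jack <- s_obs + q1 * (q - 1) / q
  list(s_obs = s_obs, q = q, q1 = q1, s_jack = s_jack,
       adequacy_ratio = s_obs / s_jack)
}

#' Sampling adequacy against the jackknife estimate
#'
#' A plot network is judged adequately sampled when the observed richness
#' reaches a stated fraction (default 80%) of the jackknife estimate.
#'
#' @inheritParams jackknife_richness
#' @param threshold Required fraction of estimated richness.
#' @return List with `ratio`, `adequate`, and the underlying jackknife fields.
#' @export
sampling_adequacy <- function(matrix, threshold = 0.8) {
  jk <- jackknife_richness(matrix)
  c(list(ratio = jk$adequacy_ratio, adequate = jk$adequacy_ratio >= threshold),
    jk)
}

#' Per-plot diversity table
#'
#' One row per plot: functional diversity (Rao's Q over the plot-contextual
#' Gower matrix), Shannon diversity, endemicity, richness, and the belt /
#' TPI-group / habitat strata.
#'
#' @param matrix An [abundance_matrix()].
#' @param traits A [trait_table()].
#' @param env An [env_table()] aligned with `matrix` by plot id.
#' @param base Shannon log base.
#' @param weighted_endemicity Also report the cover-weighted endemicity
#'   variant (column `endemicity_w`).
#' @inheritParams gower_matrix
#' @return Data.frame with columns `plot_id`, `fd_rao`, `sd_shannon`,
#'   `endemicity` (optionally `endemicity_w`), `richness`, `elevation`, `tpi`,
#'   `belt`, `tpi_group`, `habitat_type`.
#' @export
diversity_table <- function(matrix, traits, env, base = exp(1),
                            weighted_endemicity = FALSE,
                            nominal_rule = "overlap",
                            missing_rule = "classical",
                            range_scope = "plot") {
  env <- env[match(rownames(matrix), env$plot_id), , drop = FALSE]
  fdg_assert(!anyNA(env$plot_id), "env table does not cover all plots",
             "fdg_value_error")
  rows <- lapply(rownames(matrix), function(pid) {
    cov <- matrix[pid, ]
    present <- names(cov)[cov > 0]
    cov <- cov[present]
    D <- gower_matrix(present, traits, nominal_rule = nominal_rule,
                      missing_rule = missing_rule, range_scope = range_scope)
    out <- data.frame(
      plot_id = pid,
      fd_rao = rao_q(cov, D),
      sd_shannon = shannon(cov, base = base),
      endemicity = endemicity(present, traits),
      richness = length(present),
      stringsAsFactors = FALSE
    )
    if (weighted_endemicity) {
      out$endemicity_w <- endemicity(present, traits, cov, weighted = TRUE)
    }
    out
  })
  div <- do.call(rbind, rows)
  div$elevation <- env$elevation
  div$tpi <- if ("tpi" %in% names(env)) env$tpi else NA_real_
  div$belt <- classify_belt(env$elevation)
  div$tpi_group <- if ("tpi" %in% names(env)) classify_tpi_group(env$tpi)
                   else NA_integer_
  div$habitat_type <- if ("habitat_type" %in% names(env)) env$habitat_type
                      else NA_integer_
  div
}
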