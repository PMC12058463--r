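# Shared fixtures: a compact trait-table builder, random small pools, and an
# independent brute-force Gower oracle that evaluates every s_ijk and w_ijk
# literally from the per-kind definitions (scalar loops, no shared code with
# gower_matrix()).

make_trait_df <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  herb <- runif(n) < 0.6
  gymno <- !herb & runif(n) < 0.15
  df <- data.frame(species_id = sprintf("s%02d", seq_len(n)),
                   endemic = runif(n) < 0.2,
                   herbaceous = herb, gymnosperm = gymno,
                   stringsAsFactors = FALSE)
  multi <- function(codes) {
    k <- sample(1:2, 1, prob = c(0.7, 0.3))
    sort(sample(codes, min(k, length(codes))))
  }
  df$life_form <- I(lapply(seq_len(n), function(i) multi(1:7)))
  df$clonality <- I(lapply(seq_len(n), function(i) multi(1:7)))
  df$nutrient_uptake <- I(lapply(seq_len(n), function(i) multi(1:9)))
  df$spinescence <- sample(0:6, n, replace = TRUE)
  df$leaf_phenology <- I(lapply(seq_len(n), function(i) {
    if (herb[i]) integer(0) else sample(1:3, 1)
  }))
  df$floral_longevity <- ifelse(gymno, NA_real_, sample(1:12, n, replace = TRUE))
  df$flowering_duration <- ifelse(gymno, NA_real_, sample(1:12, n, replace = TRUE))
  df$dispersal_strategy <- I(lapply(seq_len(n), function(i) multi(1:7)))
  df
}

make_traits <- function(n, seed = NULL, ...) {
  df <- make_trait_df(n, seed)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  trait_table(df)
}

# Independent oracle: naive per-pair, per-trait evaluation.
oracle_gower <- function(pool, traits, missing_rule = "classical") {
  schema <- attr(traits, "schema")
  idx <- match(pool, traits$species_id)
  m <- length(pool)
  d <- matrix(0, m, m, dimnames = list(pool, pool))
  get_val <- function(tn, i) traits[[tn]][idx[i]]
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (j == k) next
    num <- 0; den <- 0
    for (tn in names(schema)) {
      def <- schema[[tn]]
      if (def$kind == "nominal") {
        a <- get_val(tn, j)[[1]]; b <- get_val(tn, k)[[1]]
        miss_a <- length(a) == 0; miss_b <- length(b) == 0
        if (miss_a && miss_b) next
        if (miss_a || miss_b) {
          if (missing_rule == "mismatch") { num <- num + 1; den <- den + 1 }
          next
        }
        s <- if (length(intersect(a, b)) > 0) 0 else 1
        num <- num + s; den <- den + 1
      } else {
        a <- traits[[tn]][idx[j]]; b <- traits[[tn]][idx[k]]
        if (is.na(a) && is.na(b)) next
        if (is.na(a) || is.na(b)) {
          if (missing_rule == "mismatch") { num <- num + 1; den <- den + 1 }
          next
        }
        vals <- traits[[tn]][idx]
        vals <- vals[!is.na(vals)]
        if (def$kind == "ordinal") {
          u <- sort(unique(vals))
          ra <- which(u == a); rb <- which(u == b)
          s <- if (length(u) == 1) 0 else abs(ra - rb) / (length(u) - 1)
        } else {
          rng <- max(vals) - min(vals)
          s <- if (rng == 0) 0 else abs(a - b) / rng
        }
        num <- num + s; den <- den + 1
      }
    }
    d[j, k] <- if (den == 0) NA_real_ else num / den
  }
  d
}

# Small abundance matrix over a given trait table.
make_cover <- function(traits, n_plots, seed = NULL, p_occ = 0.6) {
  if (!is.null(seed)) set.seed(seed)
  n_sp <- nrow(traits)
  repeat {
    m <- matrix(ifelse(runif(n_plots * n_sp) < p_occ,
                       sample(1:9, n_plots * n_sp, replace = TRUE), 0L),
                n_plots, n_sp,
                dimnames = list(sprintf("p%02d", seq_len(n_plots)),
                                traits$species_id))
    storage.mode(m) <- "integer"
    if (all(rowSums(m > 0) > 0) && all(colSums(m > 0) > 0)) return(
      abundance_matrix(m, traits))
  }
}

small_sim_config <- function(seed, ...) {
  sim_config(seed = seed, n_species = 250, n_plots = 60,
             target_records = 1500, ...)
}
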