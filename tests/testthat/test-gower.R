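test_that("per-trait discordance follows the per-kind rules", {
  lf <- trait_definition("life_form")
  expect_equal(trait_discordance(lf, 1L, 1L)$s, 0)
  expect_equal(trait_discordance(lf, 1L, 2L)$s, 1)
  expect_equal(trait_discordance(lf, c(1L, 3L), 3L)$s, 0)  # overlapping sets
  expect_equal(trait_discordance(lf, c(1L, 3L), c(2L, 4L))$s, 1)
  expect_equal(
    trait_discordance(lf, c(1L, 3L), 3L, nominal_rule = "jaccard")$s, 0.5)

  fd <- trait_definition("flowering_duration")
  r <- trait_discordance(fd, 3, 6, pool_values = c(1, 3, 6, 12))
  expect_equal(r$s, 3 / 11)
  expect_equal(r$w, 1)

  fl <- trait_definition("floral_longevity")
  # four distinct pool values: the extremes sit at ranks 1 and 4 -> s = 1
  expect_equal(trait_discordance(fl, 2, 8, pool_values = c(2, 3, 5, 8))$s, 1)
  expect_equal(trait_discordance(fl, 3, 5, pool_values = c(2, 3, 5, 8))$s, 1 / 3)

  # zero pool range: no information, no penalty
  expect_equal(trait_discordance(fd, 4, 4, pool_values = c(4, 4, 4))$s, 0)

  # missingness: both missing drops the trait; one-sided depends on the rule
  expect_equal(trait_discordance(fd, NA, NA, pool_values = 1:5)$w, 0)
  expect_equal(trait_discordance(fd, NA, 3, pool_values = 1:5)$w, 0)
  r <- trait_discordance(fd, NA, 3, pool_values = 1:5, missing_rule = "mismatch")
  expect_equal(r$w, 1)
  expect_equal(r$s, 1)
})

test_that("min-max standardization maps extremes to 0/1 and constants to 0", {
  expect_equal(minmax_standardize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_standardize(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(minmax_standardize(c(1, 12)), c(0, 1))
})

test_that("gower_matrix agrees with the brute-force oracle on enumerated pools", {
  for (seed in 1:12) {
    n <- sample(2:6, 1)
    traits <- make_traits(n, seed = seed)
    pool <- traits$species_id
    for (rule in c("classical", "mismatch")) {
      d <- gower_matrix(pool, traits, missing_rule = rule)
      o <- oracle_gower(pool, traits, missing_rule = rule)
      diag(o) <- 0
      expect_equal(d, o, tolerance = 1e-12,
                   label = sprintf("seed %d rule %s", seed, rule))
    }
  }
})

test_that("gower_matrix is symmetric, bounded and zero on the diagonal", {
  for (seed in 21:26) {
    traits <- make_traits(sample(3:8, 1), seed = seed)
    d <- gower_matrix(traits$species_id, traits)
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(unname(diag(d)), rep(0, nrow(d)))
  }
})

test_that("identical species score zero; adding an agreeing trait cannot raise d", {
  df <- make_trait_df(2, seed = 31)
  for (tn in names(default_trait_schema())) df[[tn]][2] <- df[[tn]][1]
  df$herbaceous[2] <- df$herbaceous[1]
  df$gymnosperm[2] <- df$gymnosperm[1]
  tt <- trait_table(df)
  expect_equal(gower_matrix(tt$species_id, tt)[1, 2], 0)

  # species disagreeing on life form only, flowering traits initially missing
  df <- make_trait_df(2, seed = 32)
  df$herbaceous <- c(FALSE, FALSE); df$gymnosperm <- c(TRUE, TRUE)
  df$life_form <- I(list(1L, 2L)); df$clonality <- I(list(1L, 1L))
  df$nutrient_uptake <- I(list(2L, 2L)); df$dispersal_strategy <- I(list(2L, 2L))
  df$spinescence <- c(0, 0); df$leaf_phenology <- I(list(1L, 1L))
  df$floral_longevity <- c(NA, NA); df$flowering_duration <- c(NA, NA)
  d_before <- gower_matrix(trait_table(df)$species_id, trait_table(df))[1, 2]
  df2 <- df
  df2$gymnosperm <- c(FALSE, FALSE)
  df2$flowering_duration <- c(4, 4)  # newly scored trait on which they agree
  df2$floral_longevity <- c(5, 5)
  tt2 <- trait_table(df2)
  d_after <- gower_matrix(tt2$species_id, tt2)[1, 2]
  expect_lte(d_after, d_before)
})

test_that("a pair sharing no applicable trait raises a named error", {
  df <- make_trait_df(2, seed = 33)
  for (tn in c("life_form", "clonality", "nutrient_uptake",
               "dispersal_strategy", "leaf_phenology")) {
    df[[tn]] <- I(list(df[[tn]][[1]], integer(0)))
  }
  df$spinescence <- c(0, NA)
  df$floral_longevity <- c(3, NA)
  df$flowering_duration <- c(3, NA)
  df$herbaceous <- c(FALSE, TRUE); df$gymnosperm <- c(FALSE, FALSE)
  tt <- trait_table(df)
  err <- tryCatch(gower_matrix(tt$species_id, tt),
                  error = function(e) conditionMessage(e))
  expect_match(err, "s01")
  expect_match(err, "s02")
  # the mismatch rule can still score the pair (one-sided presence counts)
  expect_equal(gower_matrix(tt$species_id, tt, missing_rule = "mismatch")[1, 2], 1)
})

test_that("gower matches cluster::daisy on complete single-valued traits", {
  library(cluster)
  set.seed(44)
  n <- 6
  df <- make_trait_df(n)
  df$herbaceous <- rep(FALSE, n); df$gymnosperm <- rep(FALSE, n)
  singles <- lapply(sample(1:7, n, replace = TRUE), identity)
  for (tn in c("life_form", "clonality", "dispersal_strategy")) {
    df[[tn]] <- I(singles)
  }
  df$nutrient_uptake <- I(lapply(sample(1:9, n, replace = TRUE), identity))
  df$leaf_phenology <- I(lapply(sample(1:3, n, replace = TRUE), identity))
  df$spinescence <- sample(0:6, n, replace = TRUE)
  df$floral_longevity <- sample(1:12, n)   # distinct: ranks = order statistics
  df$flowering_duration <- sample(1:12, n, replace = TRUE)
  tt <- trait_table(df)
  d <- gower_matrix(tt$species_id, tt)

  daisy_df <- data.frame(
    life_form = factor(unlist(singles)),
    clonality = factor(unlist(singles)),
    nutrient_uptake = factor(unlist(df$nutrient_uptake)),
    spinescence = ordered(df$spinescence),
    leaf_phenology = factor(unlist(df$leaf_phenology)),
    floral_longevity = ordered(df$floral_longevity),
    flowering_duration = df$flowering_duration,
    dispersal_strategy = factor(unlist(singles)))
  dd <- as.matrix(daisy(daisy_df, metric = "gower"))
  expect_equal(unname(d), unname(dd), tolerance = 1e-10)
})
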