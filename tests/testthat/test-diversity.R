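test_that("Rao's Q expands the double sum and reduces to Gini-Simpson at d = 1", {
  expect_equal(rao_q(5, matrix(0, 1, 1)), 0)           # single species

  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(rao_q(c(4, 4), D), 0.5)                 # p = (1/2, 1/2), d = 1

  set.seed(10)
  cov <- sample(1:9, 6, replace = TRUE)
  D1 <- matrix(1, 6, 6); diag(D1) <- 0
  p <- cov / sum(cov)
  expect_equal(rao_q(cov, D1), 1 - sum(p^2))           # Gini-Simpson

  expect_error(rao_q(c(1, 2), matrix(0, 3, 3)), class = "fdg_value_error")
})

test_that("Rao's Q is label-invariant, bounded by max d, and falls under redundancy", {
  set.seed(11)
  n <- 5
  D <- matrix(runif(n^2, 0, 1), n, n); D <- (D + t(D)) / 2; diag(D) <- 0
  cov <- sample(1:9, n, replace = TRUE)
  perm <- sample(n)
  expect_equal(rao_q(cov, D), rao_q(cov[perm], D[perm, perm]))
  expect_lte(rao_q(cov, D), max(D))
  expect_equal(rao_q(cov, matrix(0, n, n)), 0)

  # adding a functionally redundant species lowers FD while richness rises
  D2 <- matrix(c(0, 1, 1, 0), 2, 2)
  fd2 <- rao_q(c(1, 1), D2)
  D3 <- rbind(cbind(D2, c(0, 1)), c(0, 1, 0))  # third species identical to sp1
  fd3 <- rao_q(c(1, 1, 1), D3)
  expect_lt(fd3, fd2)
})

test_that("Shannon index matches closed forms and its richness bound", {
  expect_equal(shannon(7), 0)
  expect_equal(shannon(c(3, 3, 3, 3)), log(4))
  expect_equal(shannon(c(2, 1, 1)), -sum(c(.5, .25, .25) * log(c(.5, .25, .25))))
  expect_equal(shannon(c(2, 1, 1)), 1.0397, tolerance = 1e-4)
  expect_equal(shannon(c(4, 4), base = 2), 1)
  set.seed(12)
  for (i in 1:20) {
    cov <- sample(1:9, sample(2:12, 1), replace = TRUE)
    expect_lte(shannon(cov), log(length(cov)) + 1e-12)
  }
})

test_that("endemicity counts endemic prevalence, optionally cover-weighted", {
  traits <- make_traits(10, seed = 13,
                        endemic = c(TRUE, TRUE, rep(FALSE, 8)))
  expect_equal(endemicity(traits$species_id, traits), 0.2)
  expect_equal(endemicity(traits$species_id[3:10], traits), 0)
  expect_equal(endemicity(traits$species_id[1:2], traits), 1)
  cov <- c(9, 1, rep(1, 8))
  expect_equal(endemicity(traits$species_id, traits, cov, weighted = TRUE),
               10 / 18)
})

test_that("first-order jackknife reproduces the worked value and its bounds", {
  # 5 plots, 10 species, exactly 3 singletons -> S_jack = 10 + 3*4/5 = 12.4
  m <- matrix(0L, 5, 10, dimnames = list(paste0("p", 1:5), paste0("s", 1:10)))
  m[, 4:10] <- 1L            # 7 species everywhere
  m[1, 1] <- 1L; m[2, 2] <- 1L; m[3, 3] <- 1L
  jk <- jackknife_richness(abundance_matrix(m))
  expect_equal(jk$s_obs, 10)
  expect_equal(jk$q1, 3)
  expect_equal(jk$s_jack, 12.4)
  adq <- sampling_adequacy(abundance_matrix(m))
  expect_equal(adq$ratio, 10 / 12.4, tolerance = 1e-12)
  expect_true(adq$adequate)
  expect_false(sampling_adequacy(abundance_matrix(m), threshold = 0.9)$adequate)

  # duplicating a plot cannot create new singletons
  m2 <- rbind(m, p6 = m[1, ])
  jk2 <- jackknife_richness(abundance_matrix(m2))
  expect_lte(jk2$q1, jk$q1)
  expect_gte(jk2$s_jack, jk2$s_obs)
  expect_error(jackknife_richness(abundance_matrix(m[1, , drop = FALSE])),
               class = "fdg_value_error")

  # no singletons -> estimate equals the observation
  m[, 1:3] <- 1L
  jk0 <- jackknife_richness(abundance_matrix(m))
  expect_equal(jk0$s_jack, jk0$s_obs)
  expect_equal(sampling_adequacy(abundance_matrix(m))$ratio, 1)
})

test_that("diversity_table composes the per-plot metrics and strata", {
  fx <- end_to_end_fixture(small_sim_config(seed = 14))
  div <- diversity_table(fx$plots, fx$traits, fx$env,
                         weighted_endemicity = TRUE)
  expect_equal(nrow(div), nrow(fx$plots))
  expect_true(all(div$fd_rao >= 0 & div$fd_rao <= 1))
  expect_true(all(div$sd_shannon >= 0))
  expect_true(all(div$endemicity >= 0 & div$endemicity <= 1))
  expect_true(all(div$richness >= 1))

  # recompute one plot independently through the low-level operations
  pid <- rownames(fx$plots)[7]
  cov <- fx$plots[pid, ]
  present <- names(cov)[cov > 0]
  D <- gower_matrix(present, fx$traits)
  i <- match(pid, div$plot_id)
  expect_equal(div$fd_rao[i], rao_q(cov[present], D), tolerance = 1e-12)
  expect_equal(div$sd_shannon[i], shannon(cov[present]), tolerance = 1e-12)
  expect_equal(div$endemicity[i], endemicity(present, fx$traits))

  # permuting plots permutes rows only
  perm <- sample(nrow(fx$plots))
  m2 <- abundance_matrix(unclass(fx$plots)[perm, , drop = FALSE], fx$traits)
  div2 <- diversity_table(m2, fx$traits, fx$env)
  expect_equal(div2[match(div$plot_id, div2$plot_id), "fd_rao"], div$fd_rao)
})
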