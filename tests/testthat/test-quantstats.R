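test_that("LS means equal arithmetic means on balanced data", {
  rec <- sim_trial(12, n_env = 4, n_rep = 2, seed = 1)
  lsm <- ls_means(rec)
  direct <- rec |>
    dplyr::group_by(genotype, trait) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  merged <- dplyr::inner_join(lsm, direct, by = c("genotype", "trait"))
  expect_equal(merged$ls_mean, merged$m, tolerance = 1e-9)
})

test_that("LS means on unbalanced data solve the two-way normal equations", {
  rec <- sim_trial(6, n_env = 3, n_rep = 2, seed = 2)
  rec <- rec[rec$trait == "oil", ]
  rec <- rec[-5, ]                      # knock out one cell
  lsm <- ls_means(rec)
  # independent solve: two-way fixed-effects normal equations via a
  # hand-built design matrix, genotype prediction averaged over envs
  g <- factor(rec$genotype); e <- factor(rec$environment)
  X <- cbind(1, stats::model.matrix(~ g - 1)[, -1],
             stats::model.matrix(~ e - 1)[, -1])
  b <- solve(crossprod(X), crossprod(X, rec$value))
  gl <- levels(g)
  pred <- vapply(seq_along(gl), function(i) {
    gi <- if (i == 1) rep(0, nlevels(g) - 1) else
      as.numeric(seq_len(nlevels(g) - 1) == (i - 1))
    mean(vapply(seq_len(nlevels(e)), function(j) {
      ej <- if (j == 1) rep(0, nlevels(e) - 1) else
        as.numeric(seq_len(nlevels(e) - 1) == (j - 1))
      sum(b * c(1, gi, ej))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(lsm$ls_mean[match(gl, lsm$genotype)], pred,
               tolerance = 1e-9)
  # a single observation is its own LS mean
  single <- tibble::tibble(genotype = "g1", environment = "e1",
                           replicate = "r1", trait = "oil", value = 212)
  expect_equal(ls_means(single)$ls_mean, 212)
})

test_that("EMS variance components recover known parameters", {
  rec <- quantstats_recovery_trial()
  vc <- anova_variance_components(rec[rec$trait == "oil", ])
  expect_lt(abs(vc$sigma2_G - 2) / 2, 0.15)
  expect_lt(abs(vc$sigma2_GE - 0.5) / 0.5, 0.15)
  expect_lt(abs(vc$sigma2_eps - 1) / 1, 0.15)
  expect_equal(vc$n_E, 4)
  expect_equal(vc$n_R, 2)
})

test_that("degenerate and unbalanced inputs are handled", {
  rec <- sim_trial(5, n_env = 2, n_rep = 2, seed = 4)
  rec <- rec[rec$trait == "oil", ]
  const <- rec
  const$value <- 3
  vc0 <- anova_variance_components(const)
  expect_equal(vc0$sigma2_G + vc0$sigma2_GE + vc0$sigma2_eps +
                 vc0$sigma2_E + vc0$sigma2_RE, 0)
  expect_error(anova_variance_components(rec[-1, ]), "balanced")

  # pure noise: genetic variance estimate stays near zero
  noise <- sim_trial(100, n_env = 4, n_rep = 2,
                     Sigma_G = matrix(0, 2, 2), sigma2_GE = 0,
                     sigma2_eps = 1, seed = 5)
  vcn <- anova_variance_components(noise[noise$trait == "oil", ])
  expect_lt(vcn$sigma2_G, 0.05)
})

test_that("the ANOVA identity reconstructs the total sum of squares", {
  rec <- sim_trial(30, n_env = 3, n_rep = 2, seed = 6)
  d <- rec[rec$trait == "protein", ]
  vc <- anova_variance_components(d)
  tss <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(vc$mean_squares * vc$df), tss,
               tolerance = 1e-6 * tss)
})

test_that("entry-mean heritability follows the variance-ratio formula", {
  vc <- list(sigma2_G = 1, sigma2_GE = 0.4, sigma2_eps = 0.8,
             n_E = 4, n_R = 2)
  expect_equal(broad_sense_heritability(vc), 1 / 1.2)
  expect_equal(broad_sense_heritability(
    list(sigma2_G = 3, sigma2_GE = 0, sigma2_eps = 0, n_E = 4, n_R = 2)), 1)
  expect_equal(broad_sense_heritability(
    list(sigma2_G = 0, sigma2_GE = 1, sigma2_eps = 1, n_E = 4, n_R = 2)), 0)
  expect_error(broad_sense_heritability(
    list(sigma2_G = 0, sigma2_GE = 0, sigma2_eps = 0, n_E = 4, n_R = 2)),
    "zero")
  # more environments and replicates push H2 upward
  h_small <- broad_sense_heritability(
    list(sigma2_G = 1, sigma2_GE = 1, sigma2_eps = 1, n_E = 2, n_R = 2))
  h_envs <- broad_sense_heritability(
    list(sigma2_G = 1, sigma2_GE = 1, sigma2_eps = 1, n_E = 6, n_R = 2))
  h_reps <- broad_sense_heritability(
    list(sigma2_G = 1, sigma2_GE = 1, sigma2_eps = 1, n_E = 2, n_R = 6))
  expect_gt(h_envs, h_small)
  expect_gt(h_reps, h_small)
})

test_that("partial genetic correlation uses the variance-of-sums identity", {
  rec <- sim_trial(60, n_env = 3, n_rep = 2, seed = 7)
  oil <- rec[rec$trait == "oil", ]
  # the same trait against itself: covariance equals the variance, r = 1
  oil2 <- oil
  oil2$trait <- "oil_copy"
  self <- partial_genetic_correlation(oil, oil2)
  expect_equal(self$r, 1)
  expect_equal(self$cov_G, self$var_G_m, tolerance = 1e-9)

  # genetically independent traits: r near zero
  ind <- sim_trial(250, n_env = 4, n_rep = 2,
                   Sigma_G = matrix(c(2, 0, 0, 2), 2), seed = 8)
  pg0 <- partial_genetic_correlation(ind[ind$trait == "oil", ],
                                     ind[ind$trait == "protein", ])
  expect_lt(abs(pg0$r), 0.15)
})

test_that("a planted genetic correlation of -0.75 is recovered", {
  Sg <- matrix(c(2, -0.75 * 2, -0.75 * 2, 2), 2)
  rec <- sim_trial(300, n_env = 4, n_rep = 2, Sigma_G = Sg, seed = 9)
  pg <- partial_genetic_correlation(rec[rec$trait == "oil", ],
                                    rec[rec$trait == "protein", ])
  expect_lt(abs(pg$r - (-0.75)), 0.1)
  # the identity-based covariance matches the direct cross-covariance of
  # per-genotype means within sampling error
  means <- rec |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value") |>
    dplyr::group_by(genotype) |>
    dplyr::summarise(oil = mean(oil), protein = mean(protein))
  expect_lt(abs(pg$cov_G - cov(means$oil, means$protein)), 0.5)
})

test_that("variance-component tidiers expose estimates and H2", {
  rec <- sim_trial(40, n_env = 3, n_rep = 2, seed = 10)
  vc <- anova_variance_components(rec[rec$trait == "oil", ])
  td <- tidy(vc)
  expect_equal(nrow(td), 5)
  expect_true(all(td$estimate >= 0))
  gl <- glance(vc)
  expect_true(gl$H2 >= 0 && gl$H2 <= 1)
})
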