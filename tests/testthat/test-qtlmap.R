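test_that("genotype probabilities match exhaustive path enumeration", {
  map <- make_grid_map(1, 10, 10)   # markers at 0 and 10; grid adds 5
  patterns <- list(c(1L, 1L), c(1L, -1L), c(-1L, -1L),
                   c(1L, NA), c(NA, NA), c(0L, 1L))  # H is uninformative
  geno <- do.call(rbind, patterns)
  colnames(geno) <- map$marker
  rownames(geno) <- sprintf("ind%03d", seq_len(nrow(geno)))
  cross <- structure(list(map = map, geno = geno, pheno = NULL),
                     class = "ril_cross")
  probs <- calc_genoprob(cross, step = 5)
  expect_equal(probs$positions$position_cM, c(0, 5, 10))
  grid <- probs$positions$position_cM
  for (i in seq_along(patterns)) {
    expect_equal(unname(probs$pA[i, ]),
                 oracle_genoprob(patterns[[i]], c(1, 3), grid),
                 tolerance = 1e-12)
  }
  # typed marker: all mass on the observed class
  expect_equal(unname(probs$pA[2, c(1, 3)]), c(1, 0))
  # fully missing individual: prior 1/2 everywhere
  expect_equal(unname(probs$pA[5, ]), rep(0.5, 3))
})

test_that("probabilities lie in [0,1] on a multi-chromosome grid", {
  cross <- simulate_ril(make_grid_map(3, 80, 10), 60, seed = 3,
                        missing_rate = 0.1)
  probs <- calc_genoprob(cross, step = 1)
  expect_true(all(probs$pA >= 0 & probs$pA <= 1))
  expect_equal(nrow(probs$positions), 3 * 81)
  expect_error(calc_genoprob(cross, step = 0), "positive")
})

test_that("single-trait scan equals the normal-equations oracle", {
  set.seed(42)
  toy <- toy_cross(n = 60)
  cross <- toy$cross
  probs <- calc_genoprob(cross, step = 2)
  y <- cross$pheno$oil
  sc <- scan_single_trait(probs, y)
  # at typed markers the HK scan equals direct regression on genotypes
  for (m in sample(nrow(cross$map), 6)) {
    x <- as.numeric(cross$geno[, m])
    i <- which(probs$positions$chromosome == cross$map$chromosome[m] &
                 probs$positions$position_cM == cross$map$position_cM[m])
    expect_equal(sc$lod[i], oracle_lod(y, x), tolerance = 1e-9)
    fit <- lm(y ~ x)
    expect_equal(sc$effect[i], unname(coef(fit)[2]), tolerance = 1e-9)
  }
  # and with covariates
  covar <- as.numeric(cross$geno[, "m2_40"])
  scc <- scan_single_trait(probs, y, covariates = cbind(covar))
  i <- which(probs$positions$chromosome == "1" &
               probs$positions$position_cM == 30)
  expect_equal(scc$lod[i],
               oracle_lod(y, as.numeric(cross$geno[, "m1_30"]), covar),
               tolerance = 1e-9)
  expect_error(scan_single_trait(probs, rep(4, length(y))),
               "zero phenotypic variance")
})

test_that("a perfect fit reports the capped LOD", {
  toy <- toy_cross(n = 40)
  probs <- calc_genoprob(toy$cross, step = 10)
  y <- as.numeric(toy$cross$geno[, "m1_30"]) * 2 + 7
  sc <- scan_single_trait(probs, y)
  i <- which(probs$positions$chromosome == "1" &
               probs$positions$position_cM == 30)
  expect_equal(sc$lod[i], 300)
})

test_that("joint LOD decomposes for orthogonalised traits and matches the oracle", {
  set.seed(7)
  toy <- toy_cross(n = 80)
  cross <- toy$cross
  probs <- calc_genoprob(cross, step = 5)
  y1 <- cross$pheno$oil
  x <- as.numeric(cross$geno[, "m1_30"])
  # orthogonalise a noise trait against {1, x, y1}: the sample residual
  # cross-covariance vanishes under both null and QTL model, so the
  # joint LOD is exactly the sum of the single-trait LODs there
  z <- rnorm(length(y1))
  y2 <- qr.resid(qr(cbind(1, x, y1)), z)
  Y <- cbind(oil = y1, noise = y2)
  i <- which(probs$positions$chromosome == "1" &
               probs$positions$position_cM == 30)
  sj <- scan_multi_trait(probs, Y)
  s1 <- scan_single_trait(probs, y1)
  s2 <- scan_single_trait(probs, y2)
  expect_equal(sj$lod[i], s1$lod[i] + s2$lod[i], tolerance = 1e-9)
  expect_equal(sj$lod[i], oracle_joint_lod(Y, x), tolerance = 1e-9)
  # generic positions also match the multivariate oracle
  for (j in c(2, 10, 20)) {
    expect_equal(sj$lod[j], oracle_joint_lod(Y, probs$X[, j]),
                 tolerance = 1e-9)
  }
  expect_error(scan_multi_trait(probs, cbind(y1, rep(1, length(y1)))),
               "rank-deficient")
  expect_error(scan_multi_trait(probs, cbind(y1, y1)), "rank-deficient")
})

test_that("permutation max-LODs match a direct per-permutation rescan", {
  toy <- toy_cross(n = 60)
  cross <- toy$cross
  probs <- calc_genoprob(cross, step = 5)
  y <- cross$pheno$protein
  pr <- permutation_threshold(probs, y, n_perm = 8, seed = 77,
                              coupled = FALSE)
  idx <- perm_schedule(length(y), 8, 77)
  manual <- vapply(seq_len(8), function(p) {
    max(scan_single_trait(probs, y[idx[, p]])$lod)
  }, numeric(1))
  expect_equal(pr$max_lod, manual, tolerance = 1e-9)
  expect_equal(pr$threshold,
               unname(quantile(pr$max_lod, 0.95, type = 7)))

  Y <- as.matrix(cross$pheno[, c("oil", "protein")])
  prj <- permutation_threshold(probs, Y, n_perm = 8, seed = 77,
                               coupled = TRUE)
  manual_j <- vapply(seq_len(8), function(p) {
    Yp <- Y[idx[, p], ]
    # coupled resampling preserves the trait correlation exactly
    expect_equal(cor(Yp[, 1], Yp[, 2]), cor(Y[, 1], Y[, 2]))
    max(scan_multi_trait(probs, Yp)$lod)
  }, numeric(1))
  expect_equal(prj$max_lod, manual_j, tolerance = 1e-9)
})

test_that("permutation thresholds behave as empirical quantiles", {
  toy <- toy_cross(n = 50)
  probs <- calc_genoprob(toy$cross, step = 10)
  y <- toy$cross$pheno$oil
  one <- permutation_threshold(probs, y, n_perm = 1, seed = 4,
                               coupled = FALSE)
  expect_equal(one$threshold, one$max_lod[1])
  many <- permutation_threshold(probs, y, n_perm = 40, seed = 4,
                                coupled = FALSE)
  qs <- vapply(c(0.5, 0.8, 0.9, 0.95),
               function(q) unname(quantile(many$max_lod, q, type = 7)),
               numeric(1))
  expect_true(all(diff(qs) >= 0))
  expect_message(
    permutation_threshold(probs, y, n_perm = 2, coupled = TRUE, seed = 1),
    "no-op")
})

test_that("joint thresholds exceed single-trait thresholds on matched data", {
  toy <- toy_cross(n = 150, h2 = 0.5)
  cross <- toy$cross
  probs <- calc_genoprob(cross, step = 2)
  Y <- as.matrix(cross$pheno[, c("oil", "protein")])
  t1 <- permutation_threshold(probs, Y[, 1], 100, seed = 9,
                              coupled = FALSE)$threshold
  t2 <- permutation_threshold(probs, Y[, 2], 100, seed = 9,
                              coupled = FALSE)$threshold
  tj <- permutation_threshold(probs, Y, 100, seed = 9)$threshold
  expect_gt(tj, max(t1, t2))
})

test_that("forward MIM search recovers planted QTLs and rejects noise", {
  toy <- toy_cross(n = 250, h2 = 0.8)
  cross <- toy$cross
  probs <- calc_genoprob(cross, step = 1)
  # protein is affected by both QTLs (chr 1 @ 30, chr 2 @ 40)
  model <- mim_forward_search(probs, cross$pheno$protein, threshold = 3.5)
  found <- tidy(model)
  expect_equal(sort(unique(found$chromosome)), c("1", "2"))
  hit1 <- any(found$chromosome == "1" & abs(found$position_cM - 30) <= 15)
  hit2 <- any(found$chromosome == "2" & abs(found$position_cM - 40) <= 15)
  expect_true(hit1 && hit2)
  expect_true(all(found$lod > 3.5))
  expect_true(all(found$ci_lo <= found$position_cM &
                    found$position_cM <= found$ci_hi))

  # oil touches only the chr 1 QTL
  m_oil <- mim_forward_search(probs, cross$pheno$oil, threshold = 3.5)
  expect_true(all(tidy(m_oil)$chromosome == "1"))

  # pure noise yields an empty model at this threshold (fixed seed)
  set.seed(123)
  null_model <- mim_forward_search(probs, rnorm(250), threshold = 3.5)
  expect_equal(nrow(tidy(null_model)), 0)
  expect_equal(glance(null_model)$n_qtl, 0)
})

test_that("joint forward search finds the pleiotropic QTL", {
  toy <- toy_cross(n = 250, h2 = 0.8)
  probs <- calc_genoprob(toy$cross, step = 1)
  Y <- as.matrix(toy$cross$pheno[, c("oil", "protein")])
  model <- mim_forward_search(probs, Y, threshold = 4.5)
  found <- tidy(model)
  expect_true(any(found$chromosome == "1" &
                    abs(found$position_cM - 30) <= 15))
  expect_true(all(c("effect_oil", "effect_protein", "pve_oil",
                    "pve_protein") %in% names(found)))
})

test_that("fitted models report effects and drop-one PVE correctly", {
  map <- make_grid_map(2, 60, 10)
  qtl <- tibble::tibble(chromosome = "1", position_cM = 30,
                        effect_oil = -6, effect_protein = 0)
  cross <- simulate_ril(map, 200, seed = 15)
  # noiseless: phenotype = mean + genetic value
  cross0 <- simulate_phenotypes(cross, qtl, trait_model(h2 = 0.5),
                                seed = 1, Sigma_e = matrix(0, 2, 2))
  probs <- calc_genoprob(cross0, step = 5)
  fit <- fit_qtl_model(probs, cross0$pheno$oil,
                       tibble::tibble(chromosome = "1", position_cM = 30))
  expect_equal(fit$qtls$effect_trait, -6, tolerance = 1e-9)
  expect_equal(fit$qtls$pve_trait, 100, tolerance = 1e-6)
  expect_equal(fit$qtls$lod, 300)

  # toy n = 10: drop-one PVE against the normal-equations oracle
  set.seed(77)
  n <- 10
  toy_map <- make_grid_map(2, 10, 10)
  g <- matrix(sample(c(1L, -1L), n * 4, TRUE), n, 4,
              dimnames = list(sprintf("ind%03d", 1:n), toy_map$marker))
  toy_cr <- structure(list(map = toy_map, geno = g, pheno = NULL),
                      class = "ril_cross")
  pr <- calc_genoprob(toy_cr, step = 10)
  y <- rnorm(n) + g[, 1] - 0.5 * g[, 3]
  pos <- tibble::tibble(chromosome = c("1", "2"), position_cM = c(0, 0))
  fit2 <- fit_qtl_model(pr, y, pos)
  X <- cbind(g[, 1], g[, 3])
  rss_full <- oracle_rss(y, cbind(1, X))
  tss <- sum((y - mean(y))^2)
  for (q in 1:2) {
    rss_wo <- oracle_rss(y, cbind(1, X[, -q]))
    expect_equal(fit2$qtls$pve_trait[q], 100 * (rss_wo - rss_full) / tss,
                 tolerance = 1e-9)
    expect_equal(fit2$qtls$lod[q], n / 2 * log10(rss_wo / rss_full),
                 tolerance = 1e-9)
  }
  expect_error(
    fit_qtl_model(pr, y, tibble::tibble(chromosome = c("1", "1"),
                                        position_cM = c(0, 0))),
    "collinear")
})

test_that("drop-one PVE recovers the planted variance fraction", {
  map <- make_grid_map(2, 60, 10)
  cross <- simulate_ril(map, 2000, seed = 19)
  # a^2 / sigma2_P = 0.25: unit effect plus residual variance 3
  set.seed(20)
  y <- as.numeric(cross$geno[, "m1_30"]) + rnorm(2000, 0, sqrt(3))
  probs <- calc_genoprob(cross, step = 5)
  fit <- fit_qtl_model(probs, y,
                       tibble::tibble(chromosome = "1", position_cM = 30))
  expect_lt(abs(fit$qtls$pve_trait - 25), 3)
})

test_that("LOD support intervals follow the drop rule", {
  tri <- tibble::tibble(chromosome = "1",
                        position_cM = seq(30, 50, by = 0.5))
  tri$lod <- 10 - abs(tri$position_cM - 40)   # slope 1 LOD per cM
  class(tri) <- c("qtl_scan", class(tri))
  expect_equal(unname(lod_support_interval(tri, "1", 40, drop = 1.5,
                                           expand = FALSE)),
               c(38.5, 41.5))
  expect_equal(unname(lod_support_interval(tri, "1", 40, drop = 1.5)),
               c(38, 42))
  # drop 0 collapses to the positions tied with the peak
  expect_equal(unname(lod_support_interval(tri, "1", 40, drop = 0,
                                           expand = FALSE)),
               c(40, 40))
  flat <- tri
  flat$lod <- 2
  expect_equal(unname(lod_support_interval(flat, "1", 40, drop = 1.5)),
               c(30, 50))
  expect_error(lod_support_interval(tri, "1", 40, drop = -1),
               "non-negative")
})
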