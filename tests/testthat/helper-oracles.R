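# Independent oracles used across the suite.  These deliberately share no
# code with the package internals: probabilities come from exhaustive
# hidden-path enumeration, LODs from explicit normal equations.

# Exhaustive 2-state hidden-path posterior P(AA) at every grid position of
# one chromosome for a single individual.  obs_row: observed codes
# (+1/0/-1/NA) at the marker loci; midx: marker indices within grid.
oracle_genoprob <- function(obs_row, midx, grid, map_function = "haldane") {
  L <- length(grid)
  R <- ril_recfrac(cm_to_recfrac(diff(grid), map_function))
  states <- as.matrix(expand.grid(rep(list(c(1, -1)), L)))
  w <- apply(states, 1, function(s) {
    p <- 0.5
    if (L > 1) {
      for (j in 2:L) {
        p <- p * if (s[j] == s[j - 1]) 1 - R[j - 1] else R[j - 1]
      }
    }
    for (k in seq_along(midx)) {
      g <- obs_row[k]
      if (!is.na(g) && g != 0 && s[midx[k]] != g) p <- 0
    }
    p
  })
  vapply(seq_len(L), function(j) {
    sum(w[states[, j] == 1]) / sum(w)
  }, numeric(1))
}

# Normal-equations residual sum of squares of y on a design matrix.
oracle_rss <- function(y, X) {
  b <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% b)^2)
}

# Single-trait LOD of y on predictor x given covariates, by direct
# least squares: (n/2) log10(RSS0 / RSS1).
oracle_lod <- function(y, x, covariates = NULL) {
  n <- length(y)
  X0 <- cbind(rep(1, n), covariates)
  n / 2 * log10(oracle_rss(y, X0) / oracle_rss(y, cbind(X0, x)))
}

# Joint two-trait LOD by explicit multivariate least squares.
oracle_joint_lod <- function(Y, x, covariates = NULL) {
  n <- nrow(Y)
  X0 <- cbind(rep(1, n), covariates)
  X1 <- cbind(X0, x)
  res <- function(X) Y - X %*% solve(crossprod(X), crossprod(X, Y))
  d <- function(E) {
    A <- crossprod(E)
    A[1, 1] * A[2, 2] - A[1, 2]^2
  }
  n / 2 * log10(d(res(X0)) / d(res(X1)))
}

# Small study cross used by several qtlmap tests: two major QTLs at
# marker positions (so no pseudomarkers are needed and the causal locus
# is typed), plus phenotypes at a fixed seed.
toy_cross <- function(n = 200, h2 = 0.8, seed = 99) {
  map <- make_grid_map(3, 60, 10)
  qtls <- tibble::tibble(qtl = c("qA", "qB"),
                         chromosome = c("1", "2"),
                         position_cM = c(30, 40),
                         effect_oil = c(-8, 0),
                         effect_protein = c(6, 9))
  cross <- simulate_ril(map, n, seed = seed)
  cross <- simulate_phenotypes(cross, qtls, trait_model(h2 = h2),
                               seed = seed + 1)
  list(cross = cross, qtls = qtls)
}

# Reconstructs the documented permutation schedule: one seed drawn up
# front, sample.int(n) per permutation in order.
perm_schedule <- function(n, n_perm, seed) {
  set.seed(seed)
  idx <- matrix(0L, n, n_perm)
  for (p in seq_len(n_perm)) idx[, p] <- sample.int(n)
  idx
}

# Shared seeded parameter-recovery trial for the variance-component
# checks (sigma2_G = 2, sigma2_GE = 0.5, sigma2_eps = 1).
quantstats_recovery_trial <- function() {
  sim_trial(200, n_env = 4, n_rep = 2,
            Sigma_G = matrix(c(2, 0, 0, 2), 2),
            sigma2_GE = 0.5, sigma2_eps = 1, seed = 3)
}
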