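#' Genotype probabilities on a cM scan grid
#'
#' Computes, for every individual and every grid position, the conditional
#' probability of the two homozygous genotype classes given all typed
#' markers on the chromosome, via the forward-backward algorithm on the
#' two-state inbred Markov chain.  The evaluation grid is the union of a
#' fixed-step grid and all marker positions.  Transition probabilities
#' between adjacent grid loci use the selfing-expanded recombination
#' fraction ([ril_recfrac()]) of the chosen map function, matching the
#' fully inbred simulation model.  Missing (and residually heterozygous)
#' marker calls are treated as uninformative and marginalised.
#'
#' @param cross A `ril_cross`.
#' @param step Grid step in cM (> 0); default 1.
#' @param map_function Passed to [cm_to_recfrac()].
#' @return A `genoprob` object: list with `positions` (tibble
#'   `chromosome`, `position_cM`, `marker` flag), `pA` (individuals x
#'   positions matrix of P(AA)), `X` (expected genotype scores
#'   `2 P(AA) - 1`), `ids`, `step`, `map_function`.
#' @export
calc_genoprob <- function(cross, step = 1,
                          map_function = c("haldane", "kosambi")) {
  stopifnot(inherits(cross, "ril_cross"))
  map_function <- match.arg(map_function)
  if (!is.numeric(step) || length(step) != 1 || step <= 0) {
    stop("`step` must be a single positive number of cM", call. = FALSE)
  }
  n <- nrow(cross$geno)
  pieces <- split_map(cross$map)
  res <- purrr::map(pieces, function(piece) {
    if (nrow(piece) == 0) stop("empty chromosome", call. = FALSE)
    pm <- piece$position_cM
    grid <- sort(unique(c(seq(min(pm), max(pm), by = step), pm)))
    midx <- match(pm, grid)
    obs <- cross$geno[, piece$marker, drop = FALSE]
    pA <- fb_two_state(obs, midx, grid, map_function)
    list(positions = tibble::tibble(chromosome = piece$chromosome[1],
                                    position_cM = grid,
                                    marker = seq_along(grid) %in% midx),
         pA = pA)
  })
  positions <- purrr::map_dfr(res, "positions")
  pA <- do.call(cbind, purrr::map(res, "pA"))
  colnames(pA) <- sprintf("%s@%g", positions$chromosome,
                          positions$position_cM)
  structure(list(positions = positions, pA = pA, X = 2 * pA - 1,
                 ids = rownames(cross$geno), step = step,
                 map_function = map_function),
            class = "genoprob")
}

# Forward-backward for the 2-state (AA/BB) chain, vectorised over
# individuals.  obs: n x n_marker matrix (+1/0/-1/NA); midx: marker
# column index within grid; grid: positions in cM.
fb_two_state <- function(obs, midx, grid, map_function) {
  n <- nrow(obs); L <- length(grid)
  R <- if (L > 1) ril_recfrac(cm_to_recfrac(diff(grid), map_function)) else numeric(0)
  eA <- matrix(1, n, L); eB <- matrix(1, n, L)
  for (k in seq_along(midx)) {
    g <- obs[, k]
    eA[, midx[k]] <- ifelse(!is.na(g) & g == -1L, 0, 1)
    eB[, midx[k]] <- ifelse(!is.na(g) & g == 1L, 0, 1)
  }
  fA <- matrix(0, n, L); fB <- matrix(0, n, L)
  fA[, 1] <- 0.5 * eA[, 1]; fB[, 1] <- 0.5 * eB[, 1]
  sc <- fA[, 1] + fB[, 1]
  fA[, 1] <- fA[, 1] / sc; fB[, 1] <- fB[, 1] / sc
  if (L > 1) {
    for (j in 2:L) {
      r <- R[j - 1]
      pa <- fA[, j - 1] * (1 - r) + fB[, j - 1] * r
      pb <- fB[, j - 1] * (1 - r) + fA[, j - 1] * r
      fA[, j] <- pa * eA[, j]; fB[, j] <- pb * eB[, j]
      sc <- fA[, j] + fB[, j]
      fA[, j] <- fA[, j] / sc; fB[, j] <- fB[, j] / sc
    }
  }
  bA <- matrix(1, n, L); bB <- matrix(1, n, L)
  if (L > 1) {
    for (j in (L - 1):1) {
      r <- R[j]
      tA <- eA[, j + 1] * bA[, j + 1]
      tB <- eB[, j + 1] * bB[, j + 1]
      bA[, j] <- (1 - r) * tA + r * tB
      bB[, j] <- (1 - r) * tB + r * tA
      sc <- bA[, j] + bB[, j]
      bA[, j] <- bA[, j] / sc; bB[, j] <- bB[, j] / sc
    }
  }
  num <- fA * bA
  num / (num + fB * bB)
}

# Expected genotype score columns at given (chromosome, position) rows.
score_at <- function(probs, positions) {
  idx <- purrr::map_int(seq_len(nrow(positions)), function(i) {
    hit <- which(probs$positions$chromosome ==
                   as.character(positions$chromosome[i]) &
                 abs(probs$positions$position_cM -
                       positions$position_cM[i]) < 1e-8)
    if (length(hit) != 1) {
      stop("position not on the scan grid", call. = FALSE)
    }
    hit
  })
  probs$X[, idx, drop = FALSE]
}

# Coerce a phenotype input (vector, matrix, or data frame possibly with
# an id column) to a numeric matrix with one column per trait.
pheno_matrix <- function(Y) {
  if (is.data.frame(Y)) {
    Y <- Y[, setdiff(names(Y), "id"), drop = FALSE]
    Y <- as.matrix(Y)
  }
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  storage.mode(Y) <- "double"
  if (anyNA(Y) || any(!is.finite(Y))) {
    stop("phenotypes must be finite and complete", call. = FALSE)
  }
  Y
}

LOD_CAP <- 300

# Core Haley-Knott scan.  Y: n x t matrix (t = 1 or 2); covariates:
# optional n x k matrix of genotype scores.  Returns the scan tibble.
hk_scan <- function(probs, Y, covariates = NULL) {
  Y <- pheno_matrix(Y)
  n <- nrow(Y)
  if (n != nrow(probs$X)) {
    stop("phenotype length does not match the cross", call. = FALSE)
  }
  M <- cbind(rep(1, n), covariates)
  qrM <- qr(M)
  Yc <- qr.resid(qrM, Y)
  Xc <- qr.resid(qrM, probs$X)
  sxx <- colSums(Xc^2)
  ok <- sxx > 1e-10
  out <- probs$positions[, c("chromosome", "position_cM")]
  if (ncol(Y) == 1) {
    yy <- sum(Yc[, 1]^2)
    if (yy < 1e-12) stop("zero phenotypic variance", call. = FALSE)
    sxy <- drop(crossprod(Xc, Yc[, 1]))
    gain <- ifelse(ok, sxy^2 / sxx, 0)
    rss1 <- pmax(yy - gain, 0)
    lod <- ifelse(rss1 < yy * 1e-300, LOD_CAP,
                  pmin(n / 2 * log10(yy / rss1), LOD_CAP))
    out$lod <- unname(lod)
    out$effect <- unname(ifelse(ok, sxy / sxx, 0))
  } else {
    if (ncol(Y) != 2) stop("joint scans support exactly two traits",
                           call. = FALSE)
    A <- crossprod(Yc)
    det0 <- A[1, 1] * A[2, 2] - A[1, 2]^2
    if (A[1, 1] < 1e-12 || A[2, 2] < 1e-12 || det0 < 1e-12 * A[1, 1] * A[2, 2]) {
      stop("rank-deficient traits: joint scan needs two linearly ",
           "independent phenotypes with variance", call. = FALSE)
    }
    c1 <- drop(crossprod(Xc, Yc[, 1]))
    c2 <- drop(crossprod(Xc, Yc[, 2]))
    g1 <- ifelse(ok, c1^2 / sxx, 0)
    g2 <- ifelse(ok, c2^2 / sxx, 0)
    g12 <- ifelse(ok, c1 * c2 / sxx, 0)
    det1 <- pmax((A[1, 1] - g1) * (A[2, 2] - g2) - (A[1, 2] - g12)^2, 0)
    lod <- ifelse(det1 < det0 * 1e-300, LOD_CAP,
                  pmin(n / 2 * log10(det0 / det1), LOD_CAP))
    out$lod <- unname(pmax(lod, 0))
    tn <- colnames(Y)
    if (is.null(tn)) tn <- c("t1", "t2")
    out[[paste0("effect_", tn[1])]] <- unname(ifelse(ok, c1 / sxx, 0))
    out[[paste0("effect_", tn[2])]] <- unname(ifelse(ok, c2 / sxx, 0))
  }
  class(out) <- c("qtl_scan", class(out))
  attr(out, "n") <- n
  attr(out, "traits") <- if (ncol(Y) == 1) colnames(Y) %||% "trait" else colnames(Y)
  out
}

#' Single-trait interval-mapping scan
#'
#' Regresses the trait on the expected genotype score at each grid
#' position (Haley-Knott regression), optionally adjusting for genotype
#' scores of already-modelled QTLs.  The LOD is the maximum-likelihood
#' ratio statistic `(n/2) log10(RSS0 / RSS1)` against the covariates-only
#' null; a perfect fit is capped at LOD 300.
#'
#' @param probs A [calc_genoprob()] result.
#' @param y Numeric trait vector (length = individuals).
#' @param covariates Optional matrix of genotype-score covariates.
#' @return A `qtl_scan` tibble: `chromosome`, `position_cM`, `lod`,
#'   `effect` (the additive effect in trait units).
#' @export
scan_single_trait <- function(probs, y, covariates = NULL) {
  hk_scan(probs, pheno_matrix(y), covariates)
}

#' Joint two-trait interval-mapping scan
#'
#' At each position, multivariate regression of both traits on the
#' expected genotype score; the joint LOD is
#' `(n/2) log10(det(Sigma0) / det(Sigma1))` with `Sigma` the
#' maximum-likelihood residual covariance under the null and the QTL
#' model.  When the sample residual cross-covariance is zero the joint
#' LOD decomposes exactly into the sum of the two single-trait LODs.
#'
#' @param probs A [calc_genoprob()] result.
#' @param Y Two-column matrix or data frame of traits.
#' @param covariates Optional matrix of genotype-score covariates.
#' @return A `qtl_scan` tibble with `lod` (joint) and per-trait effects.
#' @export
scan_multi_trait <- function(probs, Y, covariates = NULL) {
  Y <- pheno_matrix(Y)
  if (ncol(Y) != 2) stop("Y must contain exactly two traits", call. = FALSE)
  hk_scan(probs, Y, covariates)
}

#' Genome-wide permutation threshold
#'
#' Permutes the individuals' phenotype rows against the genotype rows,
#' records the genome-wide maximum LOD of each permuted dataset, and
#' returns the empirical `q`-quantile (type-7, linearly interpolated).
#' With two traits and `coupled = TRUE` (the default) the trait rows are
#' permuted as units, preserving the sample trait correlation exactly in
#' every permuted dataset.  The full permutation schedule is drawn up
#' front from `seed`, so single- and joint-trait runs given the same seed
#' share identical permutations.
#'
#' @param probs A [calc_genoprob()] result.
#' @param Y One trait vector or a two-column trait matrix/data frame.
#' @param n_perm Number of permutations (>= 1); default 1000.
#' @param q Quantile in (0, 1); default 0.95.
#' @param coupled Couple the trait rows during resampling (two traits).
#' @param seed Optional integer seed.
#' @return A `qtl_perm` object: `max_lod` (per permutation), `threshold`,
#'   `n_perm`, `q`, `coupled`, `seed`.
#' @export
permutation_threshold <- function(probs, Y, n_perm = 1000, q = 0.95,
                                  coupled = TRUE, seed = NULL) {
  stopifnot(n_perm >= 1, q > 0, q < 1)
  Y <- pheno_matrix(Y)
  n <- nrow(Y)
  if (ncol(Y) == 1 && coupled) {
    message("coupled resampling requested with a single trait; no-op")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(0L, n, n_perm)
  for (p in seq_len(n_perm)) idx[, p] <- sample.int(n)
  idx2 <- NULL
  if (ncol(Y) == 2 && !coupled) {
    idx2 <- matrix(0L, n, n_perm)
    for (p in seq_len(n_perm)) idx2[, p] <- sample.int(n)
  }
  Xc <- sweep(probs$X, 2, colMeans(probs$X))
  sxx <- colSums(Xc^2)
  ok <- sxx > 1e-10
  sxx_safe <- ifelse(ok, sxx, 1)
  if (ncol(Y) == 1) {
    yc <- Y[, 1] - mean(Y[, 1])
    yy <- sum(yc^2)
    if (yy < 1e-12) stop("zero phenotypic variance", call. = FALSE)
    Yp <- matrix(yc[idx], n, n_perm)
    S <- crossprod(Xc, Yp)
    gain <- S^2 / sxx_safe
    gain[!ok, ] <- 0
    rss1 <- pmax(yy - gain, yy * 1e-12)
    max_lod <- apply(n / 2 * log10(yy / rss1), 2, max)
  } else {
    y1 <- Y[, 1] - mean(Y[, 1]); y2 <- Y[, 2] - mean(Y[, 2])
    a11 <- sum(y1^2); a22 <- sum(y2^2)
    Y1p <- matrix(y1[idx], n, n_perm)
    Y2p <- matrix(y2[if (is.null(idx2)) idx else idx2], n, n_perm)
    a12 <- colSums(Y1p * Y2p)          # constant when coupled
    det0 <- a11 * a22 - a12^2
    C1 <- crossprod(Xc, Y1p); C2 <- crossprod(Xc, Y2p)
    G1 <- C1^2 / sxx_safe; G2 <- C2^2 / sxx_safe
    G12 <- C1 * C2 / sxx_safe
    G1[!ok, ] <- 0; G2[!ok, ] <- 0; G12[!ok, ] <- 0
    A12 <- matrix(a12, nrow(G1), n_perm, byrow = TRUE)
    det1 <- (a11 - G1) * (a22 - G2) - (A12 - G12)^2
    det1 <- pmax(det1, matrix(det0, nrow(G1), n_perm, byrow = TRUE) * 1e-12)
    lod <- sweep(-n / 2 * log10(det1), 2, n / 2 * log10(det0), "+")
    max_lod <- apply(lod, 2, max)
  }
  structure(list(max_lod = as.numeric(max_lod),
                 threshold = unname(stats::quantile(max_lod, q, type = 7)),
                 n_perm = n_perm, q = q,
                 coupled = coupled && ncol(Y) == 2, seed = seed,
                 n_traits = ncol(Y)),
            class = "qtl_perm")
}

#' @export
print.qtl_perm <- function(x, ...) {
  cat(sprintf(
    "Permutation threshold: %.3f (q = %.2f, %d permutations, %s)\n",
    x$threshold, x$q, x$n_perm,
    if (x$n_traits == 2) {
      if (x$coupled) "joint, coupled resampling" else "joint, uncoupled"
    } else "single trait"))
  invisible(x)
}

#' Forward-selection multiple interval mapping
#'
#' Builds a multiple-QTL model by iterative forward selection: scan with
#' the already-selected QTLs' genotype scores as covariates, add the
#' highest conditional peak that exceeds `threshold` and lies outside
#' `exclusion_window` cM of every selected QTL on the same chromosome,
#' and refit all effects jointly after each addition.  Stops at `max_qtl`
#' QTLs or when no qualifying peak remains.  Works for one trait (ST-MIM)
#' or two traits jointly (MT-MIM) depending on `Y`.
#'
#' @param probs A [calc_genoprob()] result.
#' @param Y Trait vector or two-column matrix/data frame.
#' @param threshold LOD threshold (> 0), typically from
#'   [permutation_threshold()].
#' @param max_qtl Maximum number of QTLs (default 5).
#' @param exclusion_window Half-width in cM of the window around selected
#'   QTLs excluded from later searches (default 15).
#' @param ci_drop LOD drop for support intervals (default 1.5).
#' @return A `qtl_model` (possibly with zero QTLs); see
#'   [fit_qtl_model()].  Each QTL row carries its conditional LOD,
#'   per-trait effects and drop-one PVE, and a `ci_lo`/`ci_hi` support
#'   interval from its conditional profile.
#' @export
mim_forward_search <- function(probs, Y, threshold, max_qtl = 5,
                               exclusion_window = 15, ci_drop = 1.5) {
  stopifnot(threshold > 0)
  Y <- pheno_matrix(Y)
  sel <- tibble::tibble(chromosome = character(), position_cM = numeric())
  repeat {
    covar <- if (nrow(sel)) score_at(probs, sel) else NULL
    # a singular conditional residual covariance (possible when the
    # simulated residual correlation is clamped at +/-1 and all QTLs are
    # already in the model) means the joint model is saturated: stop.
    sc <- tryCatch(hk_scan(probs, Y, covar), error = function(e) {
      if (nrow(sel) > 0 && grepl("rank-deficient", conditionMessage(e))) {
        NULL
      } else {
        stop(e)
      }
    })
    if (is.null(sc)) break
    excl <- rep(FALSE, nrow(sc))
    for (i in seq_len(nrow(sel))) {
      excl <- excl | (sc$chromosome == sel$chromosome[i] &
                        abs(sc$position_cM - sel$position_cM[i]) <=
                          exclusion_window)
    }
    if (all(excl)) break
    cand <- which(!excl)
    best <- cand[which.max(sc$lod[cand])]
    if (sc$lod[best] <= threshold) break
    sel <- dplyr::bind_rows(sel, sc[best, c("chromosome", "position_cM")])
    if (nrow(sel) >= max_qtl) break
  }
  if (nrow(sel) == 0) {
    return(empty_qtl_model(Y, threshold))
  }
  model <- fit_qtl_model(probs, Y, sel)
  model$threshold <- threshold
  # support intervals and conditional profiles per QTL
  ci <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    others <- sel[-i, , drop = FALSE]
    covar <- if (nrow(others)) score_at(probs, others) else NULL
    prof <- hk_scan(probs, Y, covar)
    iv <- lod_support_interval(prof, sel$chromosome[i], sel$position_cM[i],
                               drop = ci_drop)
    tibble::tibble(ci_lo = iv[[1]], ci_hi = iv[[2]])
  })
  model$qtls$ci_lo <- ci$ci_lo
  model$qtls$ci_hi <- ci$ci_hi
  model
}

empty_qtl_model <- function(Y, threshold = NA_real_) {
  tn <- colnames(Y)
  if (is.null(tn)) tn <- if (ncol(Y) == 1) "trait" else c("t1", "t2")
  q <- tibble::tibble(chromosome = character(), position_cM = numeric())
  for (t in tn) q[[paste0("effect_", t)]] <- numeric()
  q$lod <- numeric()
  for (t in tn) q[[paste0("pve_", t)]] <- numeric()
  q$ci_lo <- numeric(); q$ci_hi <- numeric()
  structure(list(qtls = q, traits = tn, n = nrow(Y),
                 threshold = threshold),
            class = "qtl_model")
}

#' Jointly fit a multiple-QTL model at fixed positions
#'
#' Least-squares fit of the trait(s) on the expected genotype scores of
#' all listed QTLs simultaneously.  Reports per-trait additive effects
#' (sign convention: positive = increasing allele from parent A), the
#' per-QTL conditional (drop-one) LOD, and the per-trait drop-one
#' percentage of phenotypic variance explained,
#' `PVE = 100 (RSS_without - RSS_full) / TSS`.
#'
#' @param probs A [calc_genoprob()] result.
#' @param Y Trait vector or two-column matrix/data frame.
#' @param positions Tibble with `chromosome` and `position_cM` rows on
#'   the scan grid.
#' @return A `qtl_model`: list with `qtls` tibble (`chromosome`,
#'   `position_cM`, `effect_*`, `lod`, `pve_*`, `ci_lo`, `ci_hi`),
#'   `traits`, `n`, `threshold` (NA here).
#' @export
fit_qtl_model <- function(probs, Y, positions) {
  Y <- pheno_matrix(Y)
  tn <- colnames(Y)
  if (is.null(tn)) tn <- if (ncol(Y) == 1) "trait" else c("t1", "t2")
  k <- nrow(positions)
  stopifnot(k >= 1)
  # collinearity guard: two QTLs on one chromosome closer than the grid step
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j &&
          as.character(positions$chromosome[i]) ==
            as.character(positions$chromosome[j]) &&
          abs(positions$position_cM[i] - positions$position_cM[j]) <
            probs$step) {
        stop("QTL positions closer than the grid step are collinear",
             call. = FALSE)
      }
    }
  }
  X <- score_at(probs, positions)
  n <- nrow(X)
  W <- cbind(1, X)
  res_full <- qr.resid(qr(W), Y)
  rss_full <- colSums(res_full^2)
  Yc <- sweep(Y, 2, colMeans(Y))
  tss <- colSums(Yc^2)
  det_full <- det_resid(res_full)
  rows <- purrr::map_dfr(seq_len(k), function(qi) {
    Wwo <- W[, -(qi + 1), drop = FALSE]
    res_wo <- qr.resid(qr(Wwo), Y)
    rss_wo <- colSums(res_wo^2)
    lod <- if (ncol(Y) == 1) {
      n / 2 * log10(max(rss_wo, 1e-300) / max(rss_full, rss_wo * 1e-300))
    } else {
      n / 2 * log10(max(det_resid(res_wo), 1e-300) /
                      max(det_full, det_resid(res_wo) * 1e-300))
    }
    out <- tibble::tibble(chromosome = as.character(positions$chromosome[qi]),
                          position_cM = positions$position_cM[qi])
    b <- qr.coef(qr(W), Y)
    for (t in seq_along(tn)) {
      out[[paste0("effect_", tn[t])]] <- unname(b[qi + 1, t])
    }
    out$lod <- min(lod, LOD_CAP)
    for (t in seq_along(tn)) {
      out[[paste0("pve_", tn[t])]] <-
        unname(100 * max(rss_wo[t] - rss_full[t], 0) / tss[t])
    }
    out$ci_lo <- NA_real_; out$ci_hi <- NA_real_
    out
  })
  structure(list(qtls = rows, traits = tn, n = n, threshold = NA_real_),
            class = "qtl_model")
}

det_resid <- function(res) {
  A <- crossprod(res)
  if (ncol(A) == 1) A[1, 1] else A[1, 1] * A[2, 2] - A[1, 2]^2
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("Multiple-QTL model: %d QTL(s), %d individuals, trait(s): %s\n",
              nrow(x$qtls), x$n, paste(x$traits, collapse = ", ")))
  if (!is.na(x$threshold)) {
    cat(sprintf("  LOD threshold: %.3f\n", x$threshold))
  }
  if (nrow(x$qtls)) print(x$qtls)
  invisible(x)
}

#' LOD support interval around a peak
#'
#' Returns the widest contiguous interval around `peak_pos` where the
#' profile stays within `drop` LOD of the peak, expanded (by default) to
#' the nearest flanking evaluation positions just outside the drop.
#'
#' @param scan A `qtl_scan` tibble.
#' @param chromosome Chromosome of the peak.
#' @param peak_pos Peak position in cM (snapped to the nearest grid
#'   position).
#' @param drop LOD drop defining the interval (default 1.5, >= 0).
#' @param expand Expand one evaluation position beyond the drop on each
#'   side (default `TRUE`).
#' @return Named numeric `c(lo, hi)` in cM.
#' @export
lod_support_interval <- function(scan, chromosome, peak_pos, drop = 1.5,
                                 expand = TRUE) {
  if (drop < 0) stop("`drop` must be non-negative", call. = FALSE)
  sub <- scan[scan$chromosome == as.character(chromosome), ]
  if (nrow(sub) == 0) stop("chromosome not in scan", call. = FALSE)
  sub <- sub[order(sub$position_cM), ]
  i0 <- which.min(abs(sub$position_cM - peak_pos))
  thr <- sub$lod[i0] - drop
  lo <- i0
  while (lo > 1 && sub$lod[lo - 1] >= thr - 1e-12) lo <- lo - 1
  hi <- i0
  while (hi < nrow(sub) && sub$lod[hi + 1] >= thr - 1e-12) hi <- hi + 1
  if (expand) {
    lo <- max(1, lo - 1)
    hi <- min(nrow(sub), hi + 1)
  }
  c(lo = sub$position_cM[lo], hi = sub$position_cM[hi])
}
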