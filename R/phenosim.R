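#' True QTL effects of the simulation study
#'
#' The five simulated oil/protein QTLs, one per chromosome, with additive
#' effects in g/kg.  Effects of 2.5 g/kg are "minor", 15 g/kg "major";
#' qSIM-4 affects oil only and qSIM-5 protein only.  Positions default to
#' 40 cM, the central marker of each 80 cM chromosome, so the causal
#' genotype is typed and regression-based scanning coincides with the
#' likelihood-based mapping it emulates (see the package vignette for
#' the attenuation that arises when causal loci fall mid-interval); the
#' genotypic value of a locus is `+a` for the parent-A homozygote and
#' `-a` for the parent-B homozygote.
#'
#' @param position_cM Position of every QTL on its chromosome (default 40).
#' @return A tibble with columns `qtl`, `chromosome`, `position_cM`,
#'   `effect_oil`, `effect_protein`.
#' @export
sim_qtl_effects <- function(position_cM = 40) {
  tibble::tibble(
    qtl            = paste0("qSIM-", 1:5),
    chromosome     = as.character(1:5),
    position_cM    = position_cM,
    effect_oil     = c(-2.5, -2.5, -15, -2.5, 0),
    effect_protein = c(2.5, 15, 15, 0, 15)
  )
}

#' Trait model for bivariate phenotype simulation
#'
#' Bundles the trait means, per-trait heritability and the target
#' phenotypic correlation between oil and protein.  Heritability is
#' defined against the QTL-generated (purely additive) genetic variance,
#' so narrow- and broad-sense coincide; both traits share a scalar `h2`
#' unless a length-2 vector is given.
#'
#' @param means Named numeric, trait means in g/kg
#'   (default `c(oil = 220, protein = 410)`).
#' @param h2 Heritability in (0, 1], scalar or length 2.
#' @param rho Target phenotypic correlation in `[-1, 1]` (default -0.7).
#' @return A `trait_model` list.
#' @export
trait_model <- function(means = c(oil = 220, protein = 410),
                        h2 = 0.5, rho = -0.7) {
  stopifnot(length(means) == 2, !is.null(names(means)))
  h2 <- rep_len(h2, 2)
  if (any(h2 <= 0) || any(h2 > 1)) {
    stop("h2 must lie in (0, 1]", call. = FALSE)
  }
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  structure(list(traits = names(means), means = means, h2 = h2, rho = rho),
            class = "trait_model")
}

# Validate a QTL-effects tibble and return the k x 2 effect matrix.
# All-zero rows are tolerated (useful for null calibration runs).
qtl_effect_matrix <- function(qtls) {
  need <- c("chromosome", "position_cM", "effect_oil", "effect_protein")
  if (!all(need %in% names(qtls))) {
    stop("qtls needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  cbind(oil = qtls$effect_oil, protein = qtls$effect_protein)
}

# Index of each QTL's locus among the cross's map rows (error if absent).
qtl_locus_index <- function(map, qtls, tol = 1e-6) {
  idx <- purrr::map_int(seq_len(nrow(qtls)), function(q) {
    hit <- which(map$chromosome == as.character(qtls$chromosome[q]) &
                   abs(map$position_cM - qtls$position_cM[q]) < tol)
    if (length(hit) != 1) {
      stop(sprintf("QTL at chr %s, %g cM has no simulated locus",
                   qtls$chromosome[q], qtls$position_cM[q]), call. = FALSE)
    }
    hit
  })
  idx
}

#' Genetic values from true QTL genotypes
#'
#' Computes per-individual genotypic values `g_it = sum_q a_qt x_iq` with
#' `x` coded `+1`/`0`/`-1` for the AA/AB/BB classes at each QTL.  QTL
#' positions must exist as loci in the cross (insert them with
#' [add_pseudomarkers()] before simulating).
#'
#' @param cross A `ril_cross` whose map contains the QTL loci.
#' @param qtls QTL-effects tibble (see [sim_qtl_effects()]).
#' @return A tibble with columns `id`, `oil`, `protein` (g/kg deviations
#'   from the population mean).
#' @export
genetic_values <- function(cross, qtls) {
  stopifnot(inherits(cross, "ril_cross"))
  A <- qtl_effect_matrix(qtls)
  idx <- qtl_locus_index(cross$map, qtls)
  X <- cross$geno[, idx, drop = FALSE]
  if (anyNA(X)) stop("QTL genotypes contain missing values", call. = FALSE)
  G <- X %*% A
  tibble::tibble(id = rownames(cross$geno),
                 oil = unname(G[, "oil"]), protein = unname(G[, "protein"]))
}

#' Expected genetic variance-covariance of the trait pair
#'
#' Under the RIL model each locus score is `+1`/`-1` with probability 1/2,
#' and two loci on the same chromosome at expanded recombination fraction
#' `R` have score correlation `1 - 2R`; loci on different chromosomes are
#' independent.  The expected genetic covariance matrix is
#' `t(A) C A` with `C` the locus score correlation matrix.
#'
#' @param qtls QTL-effects tibble.
#' @param map Optional map tibble used to account for linkage between
#'   QTLs on a shared chromosome; `NULL` (default) treats all QTLs as
#'   unlinked, which is exact for the study design of one QTL per
#'   chromosome.
#' @param map_function Passed to [cm_to_recfrac()].
#' @return A 2 x 2 matrix with dimnames `oil`/`protein`.
#' @export
genetic_covariance <- function(qtls, map = NULL,
                               map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  A <- qtl_effect_matrix(qtls)
  k <- nrow(A)
  C <- diag(1, k)
  if (!is.null(map)) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i != j &&
            as.character(qtls$chromosome[i]) ==
            as.character(qtls$chromosome[j])) {
          d <- abs(qtls$position_cM[i] - qtls$position_cM[j])
          R <- ril_recfrac(cm_to_recfrac(d, map_function))
          C[i, j] <- 1 - 2 * R
        }
      }
    }
  } else if (anyDuplicated(as.character(qtls$chromosome))) {
    warning("QTLs share a chromosome but no map was given; ",
            "treating them as unlinked", call. = FALSE)
  }
  Sigma_G <- t(A) %*% C %*% A
  dimnames(Sigma_G) <- list(colnames(A), colnames(A))
  Sigma_G
}

#' Solve the residual covariance that realises h2 and the target correlation
#'
#' Per-trait residual variance is set from the heritability identity
#' `sigma2_e = sigma2_G (1 - h2) / h2`, and the residual covariance is
#' chosen so the total phenotypic covariance equals
#' `rho * sigma_P_oil * sigma_P_protein`.  When the implied residual
#' correlation falls outside `[-1, 1]` it is clamped to the boundary and
#' the achievable (realised) phenotypic correlation is reported; the
#' marginal structure (means, heritabilities) is never altered.
#'
#' @inheritParams genetic_covariance
#' @param model A [trait_model()].
#' @return A list: `Sigma_e` (2 x 2 residual covariance), `Sigma_G`,
#'   `Sigma_P`, `rho_target`, `rho_implied_residual`, `clamped` (logical)
#'   and `rho_realized`.
#' @export
solve_residual_covariance <- function(qtls, model, map = NULL,
                                      map_function = c("haldane", "kosambi")) {
  stopifnot(inherits(model, "trait_model"))
  map_function <- match.arg(map_function)
  Sigma_G <- genetic_covariance(qtls, map, map_function)
  vG <- diag(Sigma_G)
  h2 <- model$h2
  if (any(vG == 0 & h2 > 0 & h2 < 1)) {
    stop("a trait with zero genetic variance cannot meet 0 < h2 < 1",
         call. = FALSE)
  }
  ve <- vG * (1 - h2) / h2
  vP <- vG / h2
  target_cov <- model$rho * sqrt(vP[1] * vP[2])
  need_cov <- target_cov - Sigma_G[1, 2]
  denom <- sqrt(ve[1] * ve[2])
  clamped <- FALSE
  if (denom == 0) {
    rho_implied <- NA_real_
    e_cov <- 0
    if (abs(need_cov) > 1e-8) clamped <- TRUE
  } else {
    rho_implied <- need_cov / denom
    e_cov <- need_cov
    if (abs(rho_implied) > 1) {
      clamped <- TRUE
      e_cov <- sign(rho_implied) * denom
      warning(sprintf(
        "implied residual correlation %.3f outside [-1, 1]; clamped",
        rho_implied), call. = FALSE)
    }
  }
  Sigma_e <- matrix(c(ve[1], e_cov, e_cov, ve[2]), 2, 2,
                    dimnames = dimnames(Sigma_G))
  Sigma_P <- Sigma_G + Sigma_e
  rho_realized <- Sigma_P[1, 2] / sqrt(Sigma_P[1, 1] * Sigma_P[2, 2])
  list(Sigma_e = Sigma_e, Sigma_G = Sigma_G, Sigma_P = Sigma_P,
       rho_target = model$rho, rho_implied_residual = rho_implied,
       clamped = clamped, rho_realized = rho_realized)
}

# Draw n rows from N(0, Sigma) via eigendecomposition (handles the
# singular clamped case where |residual correlation| = 1).
rmvn <- function(n, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Z <- matrix(stats::rnorm(n * ncol(Sigma)), n)
  Z %*% (t(e$vectors) * sqrt(lam))
}

#' Simulate correlated oil/protein phenotypes
#'
#' Adds to the cross a phenotype table
#' `phenotype = mean + genetic value + bivariate normal residual`, with
#' residual covariance from [solve_residual_covariance()].
#'
#' @param cross A `ril_cross` containing the QTL loci.
#' @param qtls QTL-effects tibble.
#' @param model A [trait_model()].
#' @param seed Optional integer seed.
#' @param map_function Passed to [cm_to_recfrac()].
#' @param Sigma_e Optional fixed 2 x 2 residual covariance, bypassing the
#'   heritability-based solver (needed e.g. for null runs with all QTL
#'   effects zero, where h2 does not define a residual scale).
#' @return The cross with `pheno` set to a tibble `id`, `oil`, `protein`
#'   (g/kg).  The residual solution is attached as attribute
#'   `"residual_solution"` of the pheno tibble.
#' @export
simulate_phenotypes <- function(cross, qtls, model, seed = NULL,
                                map_function = c("haldane", "kosambi"),
                                Sigma_e = NULL) {
  stopifnot(inherits(cross, "ril_cross"), inherits(model, "trait_model"))
  map_function <- match.arg(map_function)
  sol <- if (is.null(Sigma_e)) {
    suppressWarnings(
      solve_residual_covariance(qtls, model, cross$map, map_function))
  } else {
    list(Sigma_e = Sigma_e, clamped = FALSE, rho_target = model$rho,
         rho_realized = if (all(diag(Sigma_e) > 0))
           Sigma_e[1, 2] / sqrt(Sigma_e[1, 1] * Sigma_e[2, 2]) else NA_real_)
  }
  gv <- genetic_values(cross, qtls)
  if (!is.null(seed)) set.seed(seed)
  E <- rmvn(nrow(cross$geno), sol$Sigma_e)
  pheno <- tibble::tibble(
    id      = gv$id,
    oil     = model$means[["oil"]] + gv$oil + E[, 1],
    protein = model$means[["protein"]] + gv$protein + E[, 2]
  )
  attr(pheno, "residual_solution") <- sol
  cross$pheno <- pheno
  cross
}

#' Write / read QTL truth as CSV
#'
#' Columns `chromosome, position_cM, effect_oil, effect_protein` (plus
#' `qtl` labels when present).  Metadata (package version, seed, ...) is
#' stored as `# key: value` comment lines.
#'
#' @param qtls QTL-effects tibble.
#' @param path File path.
#' @param metadata Named list written as comment headers.
#' @return `write_qtl_csv()` returns `path` invisibly; `read_qtl_csv()`
#'   the tibble.
#' @export
write_qtl_csv <- function(qtls, path, metadata = list()) {
  write_with_meta(qtls, path, metadata, delim = ",")
}

#' @rdname write_qtl_csv
#' @export
read_qtl_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(chromosome = readr::col_character()))
}
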