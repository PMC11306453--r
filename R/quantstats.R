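#' Least-squares means per genotype
#'
#' Computes per-genotype LS means of a trait from multi-environment trial
#' records, using the two-way fixed-effects model
#' `value ~ genotype + environment` (predictions averaged over all
#' environment levels).  For balanced data this equals the arithmetic
#' mean over environments and replicates; for unbalanced data it is the
#' genotype-adjusted mean from the normal equations.
#'
#' @param records Long tibble with columns `genotype`, `environment`,
#'   `replicate`, `trait`, `value`.  May contain several traits.
#' @return A tibble `genotype`, `trait`, `ls_mean`.
#' @export
ls_means <- function(records) {
  check_records(records)
  records |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(d, key) {
      d$genotype <- factor(d$genotype)
      d$environment <- factor(d$environment)
      if (nlevels(d$environment) > 1) {
        fit <- stats::lm(value ~ genotype + environment, data = d)
        grid <- expand.grid(genotype = levels(d$genotype),
                            environment = levels(d$environment))
        grid$pred <- stats::predict(fit, newdata = grid)
        out <- grid |>
          dplyr::group_by(genotype = .data$genotype) |>
          dplyr::summarise(ls_mean = mean(.data$pred), .groups = "drop")
      } else {
        out <- d |>
          dplyr::group_by(genotype = .data$genotype) |>
          dplyr::summarise(ls_mean = mean(.data$value), .groups = "drop")
      }
      out$genotype <- as.character(out$genotype)
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::select("genotype", "trait", "ls_mean")
}

check_records <- function(records, one_trait = FALSE) {
  need <- c("genotype", "environment", "replicate", "trait", "value")
  if (!all(need %in% names(records))) {
    stop("records needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records[, c("genotype", "environment", "replicate",
                                "trait")])) {
    stop("duplicate (genotype, environment, replicate, trait) keys",
         call. = FALSE)
  }
  counts <- table(records$genotype, records$trait)
  if (any(counts == 0)) {
    stop("every genotype needs at least one observation per trait",
         call. = FALSE)
  }
  if (one_trait && length(unique(records$trait)) != 1) {
    stop("records must contain exactly one trait here", call. = FALSE)
  }
  invisible(records)
}

#' ANOVA variance components for a balanced multi-environment trial
#'
#' Expected-mean-squares (method-of-moments) estimators for the fully
#' random model
#' `Y_ijk = mu + G_i + E_j + R(E)_jk + GE_ij + eps_ijk`
#' on a balanced design (every genotype observed in every environment and
#' replicate).  Negative solutions are truncated to zero, with the raw
#' values retained.
#'
#' @param records Long tibble with a single trait (columns as in
#'   [ls_means()]).
#' @return A `variance_components` list: `sigma2_G`, `sigma2_E`,
#'   `sigma2_GE`, `sigma2_RE`, `sigma2_eps`, `n_E`, `n_R`, `n_G`,
#'   `raw` (untruncated estimates), `truncated` (logical flags),
#'   `mean_squares`.
#' @export
anova_variance_components <- function(records) {
  check_records(records, one_trait = TRUE)
  d <- records
  d$G <- factor(d$genotype)
  d$E <- factor(d$environment)
  d$R <- factor(d$replicate)
  n_G <- nlevels(d$G); n_E <- nlevels(d$E); n_R <- nlevels(d$R)
  counts <- table(d$G, d$E, d$R)
  if (any(counts != 1)) {
    stop("design must be balanced: every genotype once in every ",
         "(environment, replicate) cell; REML for unbalanced data is ",
         "out of scope", call. = FALSE)
  }
  fit <- stats::aov(value ~ G + E + E:R + G:E, data = d)
  tab <- summary(fit)[[1]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  df <- tab[["Df"]]
  names(df) <- names(ms)
  ms_err <- if ("Residuals" %in% names(ms)) ms[["Residuals"]] else 0
  ms_G <- ms[["G"]]; ms_E <- ms[["E"]]
  ms_RE <- ms[["E:R"]]; ms_GE <- ms[["G:E"]]
  raw <- c(
    sigma2_G   = (ms_G - ms_GE) / (n_E * n_R),
    sigma2_E   = (ms_E - ms_GE - ms_RE + ms_err) / (n_G * n_R),
    sigma2_GE  = (ms_GE - ms_err) / n_R,
    sigma2_RE  = (ms_RE - ms_err) / n_G,
    sigma2_eps = ms_err
  )
  est <- pmax(raw, 0)
  structure(list(sigma2_G = est[["sigma2_G"]], sigma2_E = est[["sigma2_E"]],
                 sigma2_GE = est[["sigma2_GE"]],
                 sigma2_RE = est[["sigma2_RE"]],
                 sigma2_eps = est[["sigma2_eps"]],
                 n_E = n_E, n_R = n_R, n_G = n_G,
                 raw = raw, truncated = raw < 0,
                 mean_squares = ms, df = df),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (EMS, balanced design):\n")
  cat(sprintf("  G: %.4g  E: %.4g  GE: %.4g  R(E): %.4g  eps: %.4g\n",
              x$sigma2_G, x$sigma2_E, x$sigma2_GE, x$sigma2_RE,
              x$sigma2_eps))
  cat(sprintf("  n_E = %d, n_R = %d, n_G = %d\n", x$n_E, x$n_R, x$n_G))
  if (any(x$truncated)) {
    cat("  (negative estimate(s) truncated to 0)\n")
  }
  invisible(x)
}

#' Entry-mean broad-sense heritability
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_GE / n_E + sigma2_eps /
#' (n_E * n_R))`: the genetic variance over the variance of entry (line)
#' means across `n_E` environments with `n_R` replicates each.
#'
#' @param vc A [anova_variance_components()] result, or a named list with
#'   `sigma2_G`, `sigma2_GE`, `sigma2_eps`, `n_E`, `n_R`.
#' @return H-squared in `[0, 1]`.
#' @export
broad_sense_heritability <- function(vc) {
  denom <- vc$sigma2_G + vc$sigma2_GE / vc$n_E +
    vc$sigma2_eps / (vc$n_E * vc$n_R)
  if (denom <= 0) stop("all variance components are zero", call. = FALSE)
  vc$sigma2_G / denom
}

#' Partial genetic correlation between two traits
#'
#' Estimates the genetic covariance through the variance-of-sums
#' identity `sigma_G(m,n) = (sigma2_G(m+n) - sigma2_Gm - sigma2_Gn) / 2`,
#' where `sigma2_G(m+n)` is the genetic variance of the per-observation
#' sum of the two traits, and returns
#' `r = sigma_G(m,n) / sqrt(sigma2_Gm * sigma2_Gn)`, clipped to
#' `[-1, 1]`.
#'
#' @param records_m,records_n Single-trait record tibbles on the same
#'   design (identical genotype/environment/replicate keys).
#' @return A list: `r`, `cov_G`, `var_G_m`, `var_G_n`, and the three
#'   `variance_components` fits.
#' @export
partial_genetic_correlation <- function(records_m, records_n) {
  check_records(records_m, one_trait = TRUE)
  check_records(records_n, one_trait = TRUE)
  key <- c("genotype", "environment", "replicate")
  merged <- dplyr::inner_join(
    records_m[, c(key, "value")], records_n[, c(key, "value")],
    by = key, suffix = c("_m", "_n"))
  if (nrow(merged) != nrow(records_m) || nrow(merged) != nrow(records_n)) {
    stop("the two traits must share the same design", call. = FALSE)
  }
  sum_rec <- merged |>
    dplyr::transmute(.data$genotype, .data$environment, .data$replicate,
                     trait = "sum", value = .data$value_m + .data$value_n)
  vc_m <- anova_variance_components(records_m)
  vc_n <- anova_variance_components(records_n)
  vc_s <- anova_variance_components(sum_rec)
  if (vc_m$sigma2_G <= 0 || vc_n$sigma2_G <= 0) {
    stop("zero genetic variance in one of the traits", call. = FALSE)
  }
  cov_G <- (vc_s$sigma2_G - vc_m$sigma2_G - vc_n$sigma2_G) / 2
  r <- cov_G / sqrt(vc_m$sigma2_G * vc_n$sigma2_G)
  r <- max(-1, min(1, r))
  list(r = r, cov_G = cov_G, var_G_m = vc_m$sigma2_G,
       var_G_n = vc_n$sigma2_G, vc_m = vc_m, vc_n = vc_n, vc_sum = vc_s)
}

#' Simulate a balanced two-trait multi-environment trial
#'
#' Generates long-format records under the fully random model used by
#' [anova_variance_components()]: genotype effects drawn bivariate normal
#' with covariance `Sigma_G` (so the true genetic correlation is
#' controlled), independent environment, replicate-within-environment,
#' genotype-by-environment and residual effects per trait.
#'
#' @param n_geno,n_env,n_rep Design sizes.
#' @param means Named length-2 trait means.
#' @param Sigma_G 2 x 2 genetic covariance matrix.
#' @param sigma2_E,sigma2_RE,sigma2_GE,sigma2_eps Per-trait variances
#'   (length-2 or scalar) of the remaining effects.
#' @param seed Optional integer seed.
#' @return A long tibble `genotype`, `environment`, `replicate`, `trait`,
#'   `value`.
#' @export
sim_trial <- function(n_geno, n_env = 4, n_rep = 2,
                      means = c(oil = 220, protein = 410),
                      Sigma_G = matrix(c(2, -1.5, -1.5, 2), 2),
                      sigma2_E = 1, sigma2_RE = 0.25, sigma2_GE = 0.5,
                      sigma2_eps = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tn <- names(means)
  sigma2_E <- rep_len(sigma2_E, 2); sigma2_RE <- rep_len(sigma2_RE, 2)
  sigma2_GE <- rep_len(sigma2_GE, 2); sigma2_eps <- rep_len(sigma2_eps, 2)
  G <- rmvn(n_geno, Sigma_G)
  genos <- sprintf("g%03d", seq_len(n_geno))
  envs <- sprintf("env%d", seq_len(n_env))
  reps <- sprintf("r%d", seq_len(n_rep))
  purrr::map_dfr(1:2, function(t) {
    E <- stats::rnorm(n_env, 0, sqrt(sigma2_E[t]))
    RE <- matrix(stats::rnorm(n_env * n_rep, 0, sqrt(sigma2_RE[t])),
                 n_env, n_rep)
    GE <- matrix(stats::rnorm(n_geno * n_env, 0, sqrt(sigma2_GE[t])),
                 n_geno, n_env)
    grid <- expand.grid(g = seq_len(n_geno), e = seq_len(n_env),
                        r = seq_len(n_rep))
    tibble::tibble(
      genotype = genos[grid$g],
      environment = envs[grid$e],
      replicate = reps[grid$r],
      trait = tn[t],
      value = means[[t]] + G[grid$g, t] + E[grid$e] +
        RE[cbind(grid$e, grid$r)] + GE[cbind(grid$g, grid$e)] +
        stats::rnorm(nrow(grid), 0, sqrt(sigma2_eps[t]))
    )
  })
}

#' Write / read trial records as long-format CSV
#'
#' @param records Records tibble (columns as in [ls_means()]).
#' @param path File path.
#' @param metadata Named list written as `# key: value` headers.
#' @export
write_records_csv <- function(records, path, metadata = list()) {
  write_with_meta(records, path, metadata, delim = ",")
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    genotype = readr::col_character(),
                    environment = readr::col_character(),
                    replicate = readr::col_character()))
}
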