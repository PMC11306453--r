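#' Configure a detection-power scenario
#'
#' Bundles everything one replicated simulation scenario needs: the map
#' grid, the true QTL effects, the trait model at one heritability level,
#' and the scan/permutation/detection settings.  Defaults reproduce the
#' study conditions: 300 fully inbred RILs on a 6 x 80 cM map with
#' markers every 10 cM, the five pleiotropic QTLs of
#' [sim_qtl_effects()], oil/protein means of 220/410 g/kg, a target
#' correlation of -0.7, a 1-cM scan, the 95th percentile of coupled
#' permutations as threshold, and a 15 cM detection radius over 20
#' replicates.
#'
#' @param h2 Heritability level of the scenario (shared by both traits).
#' @param n_ind Individuals per replicate (default 300).
#' @param n_chr,chr_length,spacing Map grid (defaults 6, 80, 10).
#' @param qtls QTL-effects tibble (default [sim_qtl_effects()]).
#' @param means,rho Trait means (g/kg) and target correlation.
#' @param n_rep Replicates (default 20).
#' @param n_perm Permutations per analysis per replicate (default 1000).
#' @param quantile Threshold quantile (default 0.95).
#' @param detection_radius Detection radius in cM (default 15, > 0).
#' @param step Scan step in cM (default 1).
#' @param max_qtl,exclusion_window Forward-search settings.
#' @param map_function Map function for simulation and scanning.
#' @param seed Base seed; all per-replicate seeds derive from it.
#' @param Sigma_e Optional fixed residual covariance forwarded to
#'   [simulate_phenotypes()] (null-calibration runs).
#' @return A `power_scenario` list.
#' @export
power_scenario <- function(h2, n_ind = 300, n_chr = 6, chr_length = 80,
                           spacing = 10, qtls = sim_qtl_effects(),
                           means = c(oil = 220, protein = 410), rho = -0.7,
                           n_rep = 20, n_perm = 1000, quantile = 0.95,
                           detection_radius = 15, step = 1, max_qtl = 5,
                           exclusion_window = 15,
                           map_function = "haldane", seed = 1,
                           Sigma_e = NULL) {
  stopifnot(detection_radius > 0, n_rep >= 1, n_perm >= 1)
  structure(list(h2 = h2, n_ind = n_ind, n_chr = n_chr,
                 chr_length = chr_length, spacing = spacing, qtls = qtls,
                 means = means, rho = rho, n_rep = n_rep, n_perm = n_perm,
                 quantile = quantile, detection_radius = detection_radius,
                 step = step, max_qtl = max_qtl,
                 exclusion_window = exclusion_window,
                 map_function = map_function, seed = seed,
                 Sigma_e = Sigma_e),
            class = "power_scenario")
}

# Deterministic sub-seed: mixes integer components with a multiplicative
# congruential step, staying below 2^31.
derive_seed <- function(...) {
  h <- 0
  for (x in c(...)) {
    h <- (h * 69069 + (as.numeric(x) %% 2147483563) + 1) %% 2147483563
  }
  as.integer(h) + 1L
}

#' Run one replicate of the power study
#'
#' Simulates a fresh RIL population and phenotypes with seeds derived
#' from the scenario's base seed, computes per-analysis permutation
#' thresholds on that replicate (oil single-trait, protein single-trait,
#' joint; all three share one permutation schedule), runs the forward
#' MIM search for each analysis, and scores detection on the final
#' conditional LOD profiles: for each true QTL the method's profile on
#' that chromosome (scan adjusted for the model's QTLs on the other
#' chromosomes) is inspected, and the QTL is detected iff some position
#' within `detection_radius` cM of the true position exceeds the
#' method's permutation threshold.  Cells where the method's trait has
#' zero true effect are `NA`; the "either_st" method is the
#' per-replicate union of the two single-trait detections over the
#' traits each QTL truly affects.
#'
#' @param scenario A [power_scenario()].
#' @param rep_index Replicate number (>= 1).
#' @return A tibble `method`, `qtl`, `detected` (logical, `NA` for
#'   zero-effect cells), plus `rep` and per-method `threshold`.
#' @export
run_replicate <- function(scenario, rep_index) {
  sc <- scenario
  h2_tag <- round(sc$h2 * 1000)
  map <- make_grid_map(sc$n_chr, sc$chr_length, sc$spacing)
  map_aug <- add_pseudomarkers(map, sc$qtls)
  cross <- simulate_ril(map_aug, sc$n_ind, sc$map_function,
                        seed = derive_seed(sc$seed, h2_tag, rep_index, 1))
  cross <- simulate_phenotypes(cross, sc$qtls,
                               trait_model(sc$means, sc$h2, sc$rho),
                               seed = derive_seed(sc$seed, h2_tag,
                                                  rep_index, 2),
                               map_function = sc$map_function,
                               Sigma_e = sc$Sigma_e)
  obs <- drop_pseudomarkers(cross)
  probs <- calc_genoprob(obs, step = sc$step,
                         map_function = sc$map_function)
  Y <- as.matrix(cross$pheno[, c("oil", "protein")])
  perm_seed <- derive_seed(sc$seed, h2_tag, rep_index, 3)
  thr_oil <- permutation_threshold(probs, Y[, 1], sc$n_perm, sc$quantile,
                                   coupled = FALSE, seed = perm_seed)
  thr_pro <- permutation_threshold(probs, Y[, 2], sc$n_perm, sc$quantile,
                                   coupled = FALSE, seed = perm_seed)
  thr_joint <- permutation_threshold(probs, Y, sc$n_perm, sc$quantile,
                                     coupled = TRUE, seed = perm_seed)
  fits <- list(
    oil_st     = mim_forward_search(probs, Y[, 1], thr_oil$threshold,
                                    sc$max_qtl, sc$exclusion_window),
    protein_st = mim_forward_search(probs, Y[, 2], thr_pro$threshold,
                                    sc$max_qtl, sc$exclusion_window),
    joint_mt   = mim_forward_search(probs, Y, thr_joint$threshold,
                                    sc$max_qtl, sc$exclusion_window)
  )
  thr <- c(oil_st = thr_oil$threshold, protein_st = thr_pro$threshold,
           joint_mt = thr_joint$threshold, either_st = NA_real_)
  # Final conditional profile of `model` on QTL q's chromosome: scan
  # adjusted for the model's QTLs on the other chromosomes.
  hit <- function(model, Ym, threshold, q) {
    chr_q <- as.character(sc$qtls$chromosome[q])
    others <- model$qtls[model$qtls$chromosome != chr_q, , drop = FALSE]
    covar <- if (nrow(others)) score_at(probs, others) else NULL
    prof <- hk_scan(probs, Ym, covar)
    any(prof$chromosome == chr_q &
          abs(prof$position_cM - sc$qtls$position_cM[q]) <=
            sc$detection_radius &
          prof$lod > threshold)
  }
  rows <- purrr::map_dfr(seq_len(nrow(sc$qtls)), function(q) {
    oil_na <- sc$qtls$effect_oil[q] == 0
    pro_na <- sc$qtls$effect_protein[q] == 0
    d_oil <- if (oil_na) NA else
      hit(fits$oil_st, Y[, 1], thr[["oil_st"]], q)
    d_pro <- if (pro_na) NA else
      hit(fits$protein_st, Y[, 2], thr[["protein_st"]], q)
    d_either <- if (oil_na && pro_na) NA else isTRUE(d_oil) | isTRUE(d_pro)
    tibble::tibble(
      method = c("oil_st", "protein_st", "either_st", "joint_mt"),
      qtl = sc$qtls$qtl[q],
      detected = c(d_oil, d_pro, d_either,
                   hit(fits$joint_mt, Y, thr[["joint_mt"]], q))
    )
  })
  rows$rep <- rep_index
  rows$threshold <- thr[rows$method]
  rows
}

#' Run a replicated power study
#'
#' Averages [run_replicate()] detection flags over replicates, yielding
#' per-method, per-QTL detection probabilities (multiples of
#' `1 / n_rep`; `NA` where the method's trait has no true effect).
#'
#' @param scenario A [power_scenario()].
#' @param progress Print a dot per replicate to stderr (default FALSE).
#' @return A `detection_table` tibble: `h2`, `method`, `qtl`, `prob`,
#'   `n_detected`, `n_rep`; the scenario is attached as attribute
#'   `"scenario"`.
#' @export
run_power_study <- function(scenario, progress = FALSE) {
  flags <- purrr::map_dfr(seq_len(scenario$n_rep), function(r) {
    if (progress) message(".", appendLF = FALSE)
    run_replicate(scenario, r)
  })
  if (progress) message("")
  out <- flags |>
    dplyr::group_by(.data$method, .data$qtl) |>
    dplyr::summarise(
      prob = if (all(is.na(.data$detected))) NA_real_
             else mean(.data$detected, na.rm = TRUE),
      n_detected = sum(.data$detected, na.rm = TRUE),
      n_rep = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(h2 = scenario$h2, .before = 1) |>
    dplyr::arrange(match(.data$method,
                         c("oil_st", "protein_st", "either_st", "joint_mt")),
                   .data$qtl)
  class(out) <- c("detection_table", class(out))
  attr(out, "scenario") <- scenario
  out
}

#' Reshape a detection table to methods-by-QTL form
#'
#' @param dt A `detection_table` (long) tibble.
#' @return A wide tibble with one row per (h2, method) and one column per
#'   QTL.
#' @export
pivot_detection <- function(dt) {
  tidyr::pivot_wider(dt[, c("h2", "method", "qtl", "prob")],
                     names_from = "qtl", values_from = "prob")
}

#' Write / read a detection table as CSV with metadata headers
#'
#' @param dt A `detection_table` tibble.
#' @param path File path.
#' @param metadata Extra named metadata for the comment header.
#' @return `path`, invisibly; the reader returns the tibble.
#' @export
write_detection_csv <- function(dt, path, metadata = list()) {
  sc <- attr(dt, "scenario")
  if (!is.null(sc)) {
    metadata <- c(list(h2 = sc$h2, n_ind = sc$n_ind, n_rep = sc$n_rep,
                       n_perm = sc$n_perm,
                       detection_radius = sc$detection_radius,
                       seed = sc$seed), metadata)
  }
  write_with_meta(dt, path, metadata, delim = ",")
}

#' @rdname write_detection_csv
#' @export
read_detection_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write a detection table as JSON (with metadata block)
#'
#' @inheritParams write_detection_csv
#' @export
write_detection_json <- function(dt, path, metadata = list()) {
  sc <- attr(dt, "scenario")
  meta <- c(list(package = "mimpower",
                 version = as.character(utils::packageVersion("mimpower"))),
            if (!is.null(sc)) list(h2 = sc$h2, n_ind = sc$n_ind,
                                   n_rep = sc$n_rep, n_perm = sc$n_perm,
                                   detection_radius = sc$detection_radius,
                                   quantile = sc$quantile, seed = sc$seed),
            metadata)
  jsonlite::write_json(list(metadata = meta, table = dt), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Plot a detection table
#'
#' Detection probability per QTL and method, faceted by heritability when
#' several levels are bound together.
#'
#' @param object A `detection_table` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot detection_table
#' @export
autoplot.detection_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$qtl, y = .data$prob,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~h2, labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Detection probability", fill = "Method") +
    ggplot2::theme_minimal()
}
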