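#' Tidy a fitted multiple-QTL model
#'
#' @param x A `qtl_model`.
#' @param ... Unused.
#' @return The per-QTL tibble: position, per-trait effects, conditional
#'   LOD, drop-one PVE and support interval.
#' @method tidy qtl_model
#' @export
tidy.qtl_model <- function(x, ...) {
  x$qtls
}

#' @rdname tidy.qtl_model
#' @method glance qtl_model
#' @export
glance.qtl_model <- function(x, ...) {
  tibble::tibble(n_qtl = nrow(x$qtls), n = x$n,
                 traits = paste(x$traits, collapse = "+"),
                 threshold = x$threshold,
                 max_lod = if (nrow(x$qtls)) max(x$qtls$lod) else NA_real_)
}

#' Tidy a permutation-threshold result
#'
#' @param x A `qtl_perm`.
#' @param ... Unused.
#' @return `tidy()`: one row per permutation with its genome-wide max
#'   LOD; `glance()`: one row with the threshold and settings.
#' @method tidy qtl_perm
#' @export
tidy.qtl_perm <- function(x, ...) {
  tibble::tibble(perm = seq_along(x$max_lod), max_lod = x$max_lod)
}

#' @rdname tidy.qtl_perm
#' @method glance qtl_perm
#' @export
glance.qtl_perm <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, q = x$q, n_perm = x$n_perm,
                 coupled = x$coupled, n_traits = x$n_traits)
}

#' Tidy variance components
#'
#' @param x A `variance_components`.
#' @param ... Unused.
#' @return One row per component with the truncated estimate, the raw
#'   estimate and a truncation flag.
#' @method tidy variance_components
#' @export
tidy.variance_components <- function(x, ...) {
  comp <- c("sigma2_G", "sigma2_E", "sigma2_GE", "sigma2_RE", "sigma2_eps")
  tibble::tibble(component = comp,
                 estimate = unlist(x[comp], use.names = FALSE),
                 raw = unname(x$raw[comp]),
                 truncated = unname(x$truncated[comp]))
}

#' @rdname tidy.variance_components
#' @method glance variance_components
#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(H2 = broad_sense_heritability(x), n_E = x$n_E,
                 n_R = x$n_R, n_G = x$n_G)
}

#' Plot a LOD profile
#'
#' LOD curve along the genome, faceted by chromosome; a dashed line
#' marks `threshold` when given.
#'
#' @param object A `qtl_scan` tibble.
#' @param threshold Optional LOD threshold to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qtl_scan
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position_cM, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}
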