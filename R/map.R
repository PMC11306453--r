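#' Build an evenly spaced grid genetic map
#'
#' Constructs a genetic map of `n_chr` chromosomes, each carrying markers at
#' `0, spacing, 2*spacing, ...` up to `chr_length` cM (the endpoint is
#' included when `chr_length` is divisible by `spacing`).  This is the map
#' layout used throughout the simulation study: six chromosomes of 80 cM
#' with a marker every 10 cM.
#'
#' @param n_chr Number of chromosomes (>= 1).
#' @param chr_length Chromosome length in cM (>= 0).
#' @param spacing Marker spacing in cM (> 0).
#'
#' @return A tibble with columns `marker`, `chromosome`, `position_cM` and
#'   `pseudo` (logical; `FALSE` for real markers).  Chromosomes are named
#'   `"1"`, `"2"`, ... and marker ids are unique genome-wide.
#'
#' @examples
#' make_grid_map(6, 80, 10)   # 54 markers
#' @export
make_grid_map <- function(n_chr, chr_length, spacing) {
  stopifnot(is.numeric(n_chr), length(n_chr) == 1, n_chr >= 1,
            is.numeric(chr_length), length(chr_length) == 1, chr_length >= 0)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stop("`spacing` must be a single positive number of cM", call. = FALSE)
  }
  pos <- seq(0, chr_length, by = spacing)
  purrr::map_dfr(seq_len(n_chr), function(ch) {
    tibble::tibble(
      marker      = sprintf("m%d_%g", ch, pos),
      chromosome  = as.character(ch),
      position_cM = pos,
      pseudo      = FALSE
    )
  })
}

#' Validate a genetic map table
#'
#' Checks the map invariants: required columns, at least one marker per
#' chromosome, strictly increasing positions within each chromosome, and
#' genome-wide unique marker ids.
#'
#' @param map A map tibble as returned by [make_grid_map()].
#' @return The map, invisibly, with a `pseudo` column added if absent.
#' @export
validate_map <- function(map) {
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(map))) {
    stop("map must have columns marker, chromosome, position_cM", call. = FALSE)
  }
  if (nrow(map) == 0) stop("map has no markers", call. = FALSE)
  if (anyDuplicated(map$marker)) {
    stop("marker ids must be unique genome-wide", call. = FALSE)
  }
  if (any(map$position_cM < 0) || anyNA(map$position_cM)) {
    stop("positions must be non-negative numbers", call. = FALSE)
  }
  bad <- map |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(ok = all(diff(.data$position_cM) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    stop("positions must be strictly increasing within each chromosome",
         call. = FALSE)
  }
  if (!"pseudo" %in% names(map)) map$pseudo <- FALSE
  invisible(map)
}

#' Convert map distance to recombination fraction
#'
#' Haldane (no crossover interference): `r = (1 - exp(-2d/100)) / 2`.
#' Kosambi (partial interference): `r = tanh(2d/100) / 2`.
#' Distances are in cM.
#'
#' @param d Distance(s) in cM, >= 0.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#'
#' @examples
#' cm_to_recfrac(10, "haldane")   # ~0.0906
#' cm_to_recfrac(10, "kosambi")   # ~0.0987
#' @export
cm_to_recfrac <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d < 0) || anyNA(d)) {
    stop("map distances must be non-negative", call. = FALSE)
  }
  m <- d / 100
  switch(map_function,
         haldane = 0.5 * (1 - exp(-2 * m)),
         kosambi = 0.5 * tanh(2 * m))
}

#' Recombinant fraction observed between loci in selfed RILs
#'
#' Repeated selfing to fixation expands a per-meiosis recombination
#' fraction `r` to `R = 2r / (1 + 2r)` between the resulting homozygous
#' genotypes (the classical inbred-line mapping expansion).
#'
#' @param r Per-meiosis recombination fraction(s) in `[0, 0.5]`.
#' @return Expanded fraction(s) in `[0, 0.5]`.
#' @export
ril_recfrac <- function(r) {
  stopifnot(all(r >= 0), all(r <= 0.5))
  2 * r / (1 + 2 * r)
}

#' Insert pseudomarkers into a map
#'
#' Adds loci (e.g. true QTL positions) to a map so that downstream
#' simulation generates genotypes at those positions.  Pseudomarkers are
#' flagged in the `pseudo` column and can be stripped from a simulated
#' cross with [drop_pseudomarkers()].  A position already present on the
#' chromosome is left as is.
#'
#' @param map A map tibble.
#' @param positions A tibble with columns `chromosome` and `position_cM`.
#' @return The augmented map, re-sorted by chromosome and position.
#' @export
add_pseudomarkers <- function(map, positions) {
  map <- validate_map(map)
  chr_order <- unique(map$chromosome)
  new <- positions |>
    dplyr::transmute(
      marker      = sprintf("q%s_%g", .data$chromosome, .data$position_cM),
      chromosome  = as.character(.data$chromosome),
      position_cM = .data$position_cM,
      pseudo      = TRUE
    )
  if (!all(new$chromosome %in% chr_order)) {
    stop("pseudomarker chromosome not present in map", call. = FALSE)
  }
  key <- paste(map$chromosome, map$position_cM)
  new <- new[!paste(new$chromosome, new$position_cM) %in% key, , drop = FALSE]
  out <- dplyr::bind_rows(map, new)
  out <- out[order(match(out$chromosome, chr_order), out$position_cM), ]
  validate_map(out)
  out
}

# Split a map into per-chromosome pieces preserving chromosome order.
split_map <- function(map) {
  split(map, factor(map$chromosome, levels = unique(map$chromosome)))
}

#' Simulate a recombinant inbred line (RIL) population
#'
#' Generates genotypes for a biparental RIL population by a
#' marker-to-marker Markov crossover process along each chromosome, with
#' adjacent-interval recombination fractions from the chosen map function.
#' Chromosomes assort independently.
#'
#' With `inbreeding = "full"` the fully inbred two-genotype-class
#' population is simulated directly: the inter-locus switch probability is
#' the selfing expansion `R = 2r/(1+2r)` of the per-meiosis fraction
#' ([ril_recfrac()]), so only the two homozygous classes occur.  With an
#' integer `inbreeding = k` (k >= 2) an F_k population is produced by
#' explicit gamete simulation through `k - 1` selfing generations from the
#' F1, retaining the expected residual heterozygosity `(1/2)^(k-1)` per
#' locus.
#'
#' @param map Map tibble (may include pseudomarkers).
#' @param n Number of individuals (>= 1).
#' @param map_function Passed to [cm_to_recfrac()].
#' @param inbreeding `"full"` (default) or an integer `k >= 2` for F_k.
#' @param seed Optional integer seed for reproducibility.
#' @param missing_rate Proportion of genotype calls masked to missing,
#'   uniformly at random (default 0).
#'
#' @return A `ril_cross` object: a list with elements `map` (the map
#'   tibble), `geno` (an `n x M` integer matrix with values `+1` (AA, the
#'   parent-A homozygote), `-1` (BB), `0` (AB) and `NA` for missing;
#'   rows are individuals, columns markers) and `pheno` (`NULL` until
#'   phenotypes are simulated).
#'
#' @examples
#' cross <- simulate_ril(make_grid_map(2, 50, 10), n = 20, seed = 1)
#' dim(cross$geno)
#' @export
simulate_ril <- function(map, n, map_function = c("haldane", "kosambi"),
                         inbreeding = "full", seed = NULL,
                         missing_rate = 0) {
  map <- validate_map(map)
  map_function <- match.arg(map_function)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  full <- identical(inbreeding, "full")
  if (!full) {
    k <- suppressWarnings(as.integer(inbreeding))
    if (is.na(k) || k < 2) {
      stop('`inbreeding` must be "full" or an integer k >= 2', call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)

  pieces <- split_map(map)
  geno <- matrix(NA_integer_, n, nrow(map),
                 dimnames = list(sprintf("ind%03d", seq_len(n)), map$marker))
  col0 <- 0L
  for (piece in pieces) {
    L <- nrow(piece)
    r <- cm_to_recfrac(diff(piece$position_cM), map_function)
    g <- if (full) {
      sim_chr_full(n, L, ril_recfrac(r))
    } else {
      sim_chr_fk(n, L, r, k)
    }
    geno[, col0 + seq_len(L)] <- g
    col0 <- col0 + L
  }
  if (missing_rate > 0) {
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  }
  structure(list(map = map, geno = geno, pheno = NULL), class = "ril_cross")
}

# Fully inbred chromosome: 2-state chain with switch probabilities R.
sim_chr_full <- function(n, L, R) {
  g <- matrix(NA_integer_, n, L)
  g[, 1] <- sample(c(1L, -1L), n, replace = TRUE)
  if (L > 1) {
    for (j in 2:L) {
      flip <- stats::runif(n) < R[j - 1]
      g[, j] <- ifelse(flip, -g[, j - 1], g[, j - 1])
    }
  }
  g
}

# One meiotic gamete per individual from haplotype pair (h1, h2),
# crossovers as a Markov switch process with adjacent fractions r.
meiosis_gamete <- function(h1, h2, r) {
  n <- nrow(h1); L <- ncol(h1)
  use2 <- matrix(FALSE, n, L)
  use2[, 1] <- stats::runif(n) < 0.5
  if (L > 1) {
    for (j in 2:L) {
      sw <- stats::runif(n) < r[j - 1]
      use2[, j] <- xor(use2[, j - 1], sw)
    }
  }
  out <- h1
  out[use2] <- h2[use2]
  out
}

# F_k chromosome via k-1 selfing generations from the F1 (hap codes 0/1).
sim_chr_fk <- function(n, L, r, k) {
  h1 <- matrix(0L, n, L)
  h2 <- matrix(1L, n, L)
  for (gen in seq_len(k - 1)) {
    g1 <- meiosis_gamete(h1, h2, r)
    g2 <- meiosis_gamete(h1, h2, r)
    h1 <- g1; h2 <- g2
  }
  1L - (h1 + h2)   # 0/0 -> +1 (AA), 0/1 -> 0 (AB), 1/1 -> -1 (BB)
}

#' @export
print.ril_cross <- function(x, ...) {
  n_chr <- length(unique(x$map$chromosome))
  cat(sprintf("RIL cross: %d individuals, %d loci on %d chromosomes\n",
              nrow(x$geno), ncol(x$geno), n_chr))
  if (any(x$map$pseudo)) {
    cat(sprintf("  (%d pseudomarker loci)\n", sum(x$map$pseudo)))
  }
  if (!is.null(x$pheno)) {
    cat(sprintf("  phenotypes: %s\n",
                paste(setdiff(names(x$pheno), "id"), collapse = ", ")))
  }
  invisible(x)
}

#' Remove pseudomarker loci from a simulated cross
#'
#' Returns the observable cross: pseudomarker (e.g. true-QTL) columns are
#' dropped from the genotype matrix and the map, emulating that real
#' marker data never includes the causal loci themselves.
#'
#' @param cross A `ril_cross`.
#' @return A `ril_cross` without pseudo loci.
#' @export
drop_pseudomarkers <- function(cross) {
  stopifnot(inherits(cross, "ril_cross"))
  keep <- !cross$map$pseudo
  structure(list(map = cross$map[keep, ],
                 geno = cross$geno[, keep, drop = FALSE],
                 pheno = cross$pheno),
            class = "ril_cross")
}

#' Genotype matrix as a tibble
#'
#' @param cross A `ril_cross`.
#' @return A tibble with an `id` column and one `A`/`H`/`B` character
#'   column per marker (`NA` for missing).
#' @export
geno_tibble <- function(cross) {
  stopifnot(inherits(cross, "ril_cross"))
  codes <- geno_to_char(cross$geno)
  out <- tibble::as_tibble(as.data.frame(codes, stringsAsFactors = FALSE))
  dplyr::bind_cols(tibble::tibble(id = rownames(cross$geno)), out)
}

geno_to_char <- function(g) {
  out <- matrix(NA_character_, nrow(g), ncol(g), dimnames = dimnames(g))
  out[!is.na(g) & g == 1L] <- "A"
  out[!is.na(g) & g == 0L] <- "H"
  out[!is.na(g) & g == -1L] <- "B"
  out
}

char_to_geno <- function(ch) {
  out <- matrix(NA_integer_, nrow(ch), ncol(ch), dimnames = dimnames(ch))
  out[ch == "A"] <- 1L
  out[ch == "H"] <- 0L
  out[ch == "B"] <- -1L
  bad <- !is.na(ch) & !ch %in% c("A", "H", "B", "-", "")
  if (any(bad)) {
    stop("unknown genotype code(s): ",
         paste(unique(ch[bad]), collapse = ", "), call. = FALSE)
  }
  out
}
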