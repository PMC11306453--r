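#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used
#' for the reported one-decimal protein-to-oil ratios), unlike base R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Protein-to-oil change ratio of a locus
#'
#' Ratio of a locus's additive effect on protein content to its additive
#' effect on oil content, reported rounded to one decimal
#' (half-away-from-zero).  Loci with high-magnitude ratios shift protein
#' much more than oil; ratios below 1 in magnitude mark oil-dominant
#' loci.
#'
#' @param a_protein,a_oil Additive effects in g/kg (vectors allowed).
#' @param digits Decimals in the report (default 1); use `NULL` for the
#'   raw ratio.
#' @return The (rounded) ratio(s).
#'
#' @examples
#' protein_to_oil_ratio(4.51, -0.94)   # -4.8
#' @export
protein_to_oil_ratio <- function(a_protein, a_oil, digits = 1) {
  if (any(a_oil == 0)) {
    stop("oil effect of zero: ratio undefined", call. = FALSE)
  }
  r <- a_protein / a_oil
  if (is.null(digits)) r else round_half_away(r, digits)
}

#' Price and crush configuration for processed-value calculations
#'
#' Baseline prices follow the 2017/18-2021/22 five-year averages used
#' for the study: $353.02 per ton of 48%-protein meal and $0.4256 per
#' pound of oil.  The crush constants (how a 60 lb bushel of seed splits
#' into extracted oil, meal and hulls/waste) are stylised, documented
#' defaults: the pricing comparisons in this package are sign- and
#' shape-level, not dollar-exact.
#'
#' @param meal_base_price $/ton paid for meal at exactly
#'   `meal_protein_cap` percent protein.
#' @param oil_price $/lb of extracted oil.
#' @param meal_protein_cap Cap in percent meal protein (default 48) above
#'   which the NOPA price plateaus.
#' @param bushel_lb Bushel weight in lb (default 60).
#' @param oil_recovery Fraction of seed oil recovered by crushing
#'   (default 0.95).
#' @param hull_fraction Fraction of bushel mass lost to hulls/waste
#'   (default 0.08); the remainder after oil extraction is meal, which
#'   retains all seed protein.
#' @return A `price_config` list.
#' @export
price_config <- function(meal_base_price = 353.02, oil_price = 0.4256,
                         meal_protein_cap = 48, bushel_lb = 60,
                         oil_recovery = 0.95, hull_fraction = 0.08) {
  vals <- c(meal_base_price, oil_price, bushel_lb, oil_recovery,
            hull_fraction)
  if (any(vals < 0)) stop("prices and fractions must be >= 0", call. = FALSE)
  if (meal_protein_cap <= 0 || meal_protein_cap >= 100) {
    stop("meal protein cap must lie in (0, 100) percent", call. = FALSE)
  }
  structure(list(meal_base_price = meal_base_price, oil_price = oil_price,
                 meal_protein_cap = meal_protein_cap, bushel_lb = bushel_lb,
                 oil_recovery = oil_recovery, hull_fraction = hull_fraction),
            class = "price_config")
}

#' Estimated processed value per bushel
#'
#' Splits a bushel of seed into extracted oil (valued at `oil_price` per
#' lb) and meal (all seed protein concentrates into the meal mass left
#' after oil extraction and hull loss).  Meal is valued per ton at a
#' protein-dependent price: under `"NOPA"` the price rises linearly with
#' meal protein up to the cap and plateaus at the base price above it
#' (a penalty below 48% and no premium above); under `"HYQ"` it stays
#' linear throughout, rewarding protein past the cap.
#'
#' @param oil,protein Seed oil and protein contents in g/kg (vectors
#'   allowed).
#' @param prices A [price_config()].
#' @param method `"NOPA"` (capped) or `"HYQ"` (uncapped).
#' @return EPV in $/bushel.
#' @export
epv_per_bushel <- function(oil, protein, prices = price_config(),
                           method = c("NOPA", "HYQ")) {
  stopifnot(inherits(prices, "price_config"))
  method <- match.arg(method)
  oil_frac <- oil / 1000
  prot_frac <- protein / 1000
  oil_lb <- prices$bushel_lb * oil_frac * prices$oil_recovery
  meal_lb <- prices$bushel_lb *
    (1 - oil_frac * prices$oil_recovery - prices$hull_fraction)
  if (any(meal_lb <= 0)) stop("composition leaves no meal mass", call. = FALSE)
  meal_protein_pct <- 100 * prices$bushel_lb * prot_frac / meal_lb
  priced_protein <- if (method == "NOPA") {
    pmin(meal_protein_pct, prices$meal_protein_cap)
  } else {
    meal_protein_pct
  }
  meal_price_ton <- prices$meal_base_price * priced_protein /
    prices$meal_protein_cap
  oil_lb * prices$oil_price + meal_lb / 2000 * meal_price_ton
}

#' Allelic effect on estimated processed value
#'
#' Difference in EPV per bushel between the mean compositions of the two
#' allele classes at a locus: `EPV(allele B means) - EPV(allele A
#' means)`, matching the trait-effect sign convention (positive =
#' value-increasing allele from parent B relative to parent A).
#'
#' @param means A two-row tibble/data frame with columns `allele`, `oil`,
#'   `protein` (g/kg); rows are matched to alleles "A" and "B" by the
#'   `allele` column, else taken in order A then B.
#' @param prices A [price_config()].
#' @param method `"NOPA"` or `"HYQ"`.
#' @return Delta EPV in $/bushel.
#' @export
allelic_epv_effect <- function(means, prices = price_config(),
                               method = c("NOPA", "HYQ")) {
  method <- match.arg(method)
  if (nrow(means) != 2 || !all(c("oil", "protein") %in% names(means))) {
    stop("`means` must have two rows and columns oil, protein",
         call. = FALSE)
  }
  ord <- if ("allele" %in% names(means)) order(means$allele) else 1:2
  a <- means[ord[1], ]; b <- means[ord[2], ]
  epv_per_bushel(b$oil, b$protein, prices, method) -
    epv_per_bushel(a$oil, a$protein, prices, method)
}

#' Per-allele mean compositions implied by additive effects
#'
#' Builds the two allele-class mean compositions `mean -/+ effect` from
#' population means and additive effects (the parent-A homozygote is
#' `mean + effect` under the positive-equals-parent-A sign convention).
#'
#' @param mean_oil,mean_protein Population means in g/kg.
#' @param a_oil,a_protein Additive effects in g/kg.
#' @return A two-row tibble `allele`, `oil`, `protein`.
#' @export
allele_means <- function(mean_oil, mean_protein, a_oil, a_protein) {
  tibble::tibble(
    allele  = c("A", "B"),
    oil     = c(mean_oil + a_oil, mean_oil - a_oil),
    protein = c(mean_protein + a_protein, mean_protein - a_protein)
  )
}
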