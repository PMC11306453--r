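---
title: "Simulating and mapping correlated seed-composition QTLs: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and mapping correlated seed-composition QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimpower)
```

`mimpower` answers one question end to end: when two traits are
strongly correlated but highly heritable, does joint (multi-trait)
interval mapping still detect QTLs that single-trait mapping misses?
This vignette documents the models behind each stage, the parameters
that matter, the numerical conventions, and what the simulation can and
cannot say about real data.

## The population simulator

Genotypes are generated for a biparental recombinant inbred line (RIL)
population on a user-defined map — by default six chromosomes of 80 cM
with markers every 10 cM.  Within a chromosome the genotype sequence is
a Markov chain over the ordered loci: the first locus is a fair draw
between the two parental homozygotes and each subsequent locus switches
parent with the recombination probability of the adjacent interval.
Chromosomes assort independently.  Two inbreeding regimes are provided:

* **`"full"` (default).**  The fully inbred end state is simulated
  directly as a two-state chain whose switch probability is the
  classical selfing expansion `R = 2r/(1+2r)` of the per-meiosis
  fraction `r`.  Only the two homozygous classes occur, which is all the
  power experiment requires.
* **`F_k` (k >= 2).**  Explicit gamete simulation through `k - 1`
  selfing generations from the F1, retaining residual heterozygosity
  `(1/2)^(k-1)` per locus, for users who want partially inbred realism.

Distances convert to recombination fractions through the Haldane map
function by default (no crossover interference — self-consistent with a
Markov crossover process); Kosambi is available everywhere for use
where partial interference is wanted.  Simulating marker-to-marker (a
Markov chain on the ordered loci, with causal loci inserted as
pseudomarkers) rather than placing continuous crossover points keeps
the process exact at every queried locus.

## The trait model

Five QTLs, one per chromosome, carry additive effects in g/kg on oil
and protein: minor effects of 2.5, major effects of 15, including one
oil-only and one protein-only locus (`sim_qtl_effects()`).  Genotypic
values are `g_t = sum_q a_qt x_q` with `x_q = ±1`; phenotypes add trait
means (220 g/kg oil, 410 g/kg protein) and a bivariate normal residual.

Two calibration constraints define the residual covariance
(`solve_residual_covariance()`):

1. per-trait heritability: `sigma2_e,t = sigma2_G,t (1 - h2)/h2`, where
   `sigma2_G,t` is the expected genetic variance `sum_q a_qt^2`
   (corrected for linkage via `1 - 2R` score correlations if two QTLs
   share a chromosome);
2. the phenotypic oil-protein correlation target (default -0.7):
   the residual covariance absorbs whatever the genetic covariance
   (-268.75 (g/kg)^2 under the default effects) does not supply.

These constraints can conflict.  At `h2 = 0.9` the residual variances
are small and the implied residual correlation falls below -1; the
solver then **clamps** the residual correlation to the boundary, keeps
the marginal structure (means, heritabilities) untouched, and reports
the achievable correlation (about -0.69) alongside a `clamped` flag.
The alternative — quietly inflating residual variance to buy more
covariance — would corrupt the heritability the scenario is named
after, so it is never done.  Heritability here is defined against the
QTL-generated variance; the model is purely additive, so narrow- and
broad-sense coincide, and both traits share the scenario's single `h2`.

## Genotype probabilities and scan engines

Scanning runs on a fixed grid (default step 1 cM, always including the
markers).  For each individual, the probability of each homozygous
class at each grid position conditional on all typed markers of the
chromosome comes from the forward-backward algorithm on the two-state
chain, with the same expanded transition fractions the simulator uses.
Missing calls — and residual heterozygotes, for which the two-state
inbred model has no state — contribute flat emissions and are
marginalised.  The unit tests pin these posteriors against exhaustive
enumeration of all hidden paths on small chromosomes.

Position-wise testing uses Haley-Knott regression on the expected
genotype score `2 P(AA) - 1`:

* single trait: `LOD = (n/2) log10(RSS0/RSS1)`;
* joint traits: `LOD = (n/2) log10(det(S0)/det(S1))` with `S` the
  maximum-likelihood residual covariance matrix.  When the sample
  residual cross-covariance vanishes the joint LOD is exactly the sum
  of the single-trait LODs, a property the tests verify.

A perfect fit (RSS or determinant underflow) reports a capped LOD of
300 rather than infinity.  Positions whose score has (conditional)
variance below 1e-10 report LOD 0.

**Why regression and not the EM mixture likelihood?**  For fully inbred
lines with complete marker data the two coincide at typed loci, and the
expected-score regression is orders of magnitude cheaper inside a
permutation loop.  The difference is *not* negligible in one situation:
conditioning on a major QTL whose causal locus lies mid-interval.  The
expected score then captures only a fraction `rho^2 < 1` of the causal
variance (about 0.81 at the centre of a 10-cM interval), and the
remainder stays in the residual, deflating conditional LODs of minor
QTLs elsewhere.  A mixture likelihood would absorb that variance in its
genotype-configuration sum.  For this reason the simulated causal loci
default to a typed marker position (40 cM, the central marker), where
regression and likelihood engines agree; `sim_qtl_effects(position_cM =)`
lets users move the QTLs mid-interval to study exactly this attenuation.

## Thresholds, model search and detection

Genome-wide significance uses permutation: trait rows are shuffled
against genotype rows, the genome-wide maximum LOD is recorded per
permutation, and the threshold is the empirical 95th percentile
(type-7, linearly interpolated; the quantile convention is recorded in
the result object).  With two traits the rows are permuted as units
("coupled"), so every permuted dataset preserves the sample trait
correlation exactly — the null hypothesis severs genotype-phenotype
association without distorting the trait pair.  One seed draws the full
permutation schedule up front, so single- and joint-trait thresholds
can share identical permutations.

Multiple-QTL models are built by forward selection: scan conditionally
on the selected QTLs' scores, admit the best peak exceeding the
threshold outside a 15-cM exclusion window of the current model, refit
jointly, and stop at five QTLs or when no peak qualifies.  The fitted
model reports per-trait effects, per-QTL conditional (drop-one) LOD,
drop-one percent variance explained, and a 1.5-LOD support interval
from each QTL's conditional profile (the widest run within 1.5 LOD of
the peak, extended one grid position outward).  If the conditional
residual covariance becomes singular — possible when the simulated
residual correlation was clamped to ±1 and every QTL is already
modelled — the search treats the model as saturated and stops.

The replicated power study (`run_power_study()`) simulates a fresh
population per replicate, computes per-analysis thresholds on that
replicate (oil, protein, joint; defaults: 1000 permutations in
interactive use, 200 in the bundled acceptance runs), runs the three
forward searches, and scores each true QTL against each method's final
conditional profile: *detected* means some position within 15 cM of the
truth exceeds the method's threshold on the profile adjusted for the
model's QTLs on the other chromosomes.  Cells whose trait has no true
effect are reported `NA`, mirroring the dash convention of detection tables;
"either ST" is the per-replicate union of the two single-trait
detections.  All randomness descends from one base seed through a
deterministic `(scenario, replicate, role)` hash, so scenarios are
comparable and any replicate can be regenerated in isolation.

Problem sizes: the bundled acceptance test runs 4 heritability levels x
20 replicates x 200 permutations x 3 analyses at n = 300, and the
calibration run uses one population of n = 5000 — sizes chosen so the
whole suite completes in well under an hour on a laptop core while
keeping the Monte-Carlo error of a 20-replicate detection probability
(binomial SE up to 0.11) explicit in the test tolerances.

## Multi-environment trial statistics

`anova_variance_components()` estimates the fully random model
`Y_ijk = mu + G_i + E_j + R(E)_jk + GE_ij + eps_ijk` by expected mean
squares on balanced designs — the estimator is exact and closed-form
there, which is what makes parameter-recovery tests crisp; unbalanced
data are rejected rather than approximated (REML is deliberately out of
scope).  Negative component solutions truncate to zero with the raw
value retained.  Entry-mean broad-sense heritability is
`H2 = sigma2_G / (sigma2_G + sigma2_GE/n_E + sigma2_eps/(n_E n_R))`.

The partial genetic correlation of two traits uses the variance-of-sums
identity `cov_G(m,n) = (sigma2_G(m+n) - sigma2_Gm - sigma2_Gn)/2`,
dividing by `sqrt(sigma2_Gm sigma2_Gn)` — the standard correlation
normalisation — and clipping to [-1, 1].  `sim_trial()` generates
balanced two-trait trials with a controlled genetic covariance matrix
so both the identity and the correlation recovery are testable.

`ls_means()` computes genotype LS means from the two-way fixed-effects
normal equations (genotype + environment), which reduce to arithmetic
means on balanced data.

## Processed-value economics

`epv_per_bushel()` splits a bushel into extracted oil, meal and
hull/waste, concentrates all seed protein into the meal, and prices oil
per pound and meal per ton at a protein-dependent price: linear below
the 48% meal-protein cap and flat above it (NOPA), or linear throughout
(HY+Q).  Baseline prices default to $353.02/ton meal and $0.4256/lb
oil.  The crush constants (60 lb bushel, 95% oil recovery, 8% hull
fraction) are stylised and configurable; at the study's mean
composition they put meal protein near 58%, comfortably above the cap,
so capped-method value differences are driven by oil alone — the
qualitative regime the sign tests exercise.  Dollar outputs are for
comparing pricing rules and allele substitutions, not for market
forecasting.  Reported protein-to-oil change ratios round half away
from zero to one decimal.

## What passing tests do and do not show

The simulator emulates idealised conditions: markers without genotyping
error, fully informative biallelic loci, no segregation distortion, no
missing data (unless masked), i.i.d. bivariate normal residuals with no
environment structure, and purely additive QTLs.  Real GBS-derived maps
bring missingness, distortion, uneven marker density and
genotype-by-environment interaction, all of which reduce power relative
to these results.  Detection probabilities here therefore bound what
comparable real studies can expect, and the package's conclusions about
ST- versus MT-MIM orderings — not absolute power levels — are the
transportable result.  Other known limitations: at most two traits
jointly; no epistasis, dominance or composite-interval cofactor
selection; no physical (bp) coordinates; and the forward search is
greedy, so closely linked QTL pairs inside one exclusion window resolve
as a single locus.
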