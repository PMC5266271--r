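---
title: "Matched-quartet factorial designs and randomization inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-quartet factorial designs and randomization inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetri)
```

## The design

quartetri implements the full chain of a 2×2 factorial experiment with
ex-ante matched blocking, as used in small field experiments on farmer
knowledge: units are matched into quartets on baseline covariates *before*
randomization, the four factorial conditions are randomized within each
quartet, and inference is carried by the randomization itself.

### Matching

`standardize_covariates()` centers each covariate by its sample mean and
scales by its sample standard deviation (n−1 denominator). Binary covariates
are standardized identically to continuous ones, which is what "equal weight
per characteristic" means on this scale. Both statistics are computed once,
on the full pre-matching sample: re-standardizing as the pool shrinks would
make the metric depend on the random draw order, an arbitrary dependence the
procedure does not need. Constant columns become all-zero columns rather
than dividing by zero.

`form_blocks()` is the greedy seed-unit procedure: draw one unit uniformly
at random from the pool, attach the remaining unit closest to it — the
Euclidean (root-sum-of-squares) distance on the standardized scale — three
successive times, emit the quartet, repeat. Two open choices are resolved as
follows:

* **Neighbour criterion.** Members 2–4 are each nearest to the *original*
  seed unit, not to the growing group's centroid; the block is "three
  matches to this first farmer". The centroid variant is available via
  `method = "centroid"` for users who prefer compact groups over
  anchor-similar ones.
* **Ties.** Equal distances are broken by the lexicographically smallest
  unit id, making the partition fully deterministic given the seed.
* **Remainders.** If the sample size is not divisible by four, the final
  `r < 4` units are excluded with a warning naming them; the design needs
  complete quartets.

Greedy matching is deliberately myopic — no optimal global matching, no
Mahalanobis distance, no re-randomization balance checks. The procedure's
value is covariate similarity *within* blocks, which it buys cheaply; the
test suite verifies that matched blocks are tighter than random partitions
on clustered covariates.

### Allocation

`assign_arms()` permutes the four arms (`Ctrl`, `Sel`, `Store`,
`Sel+Store`) uniformly at random within each block, independently across
blocks. Consequences used everywhere downstream: each arm appears exactly
once per block, and each main-effect factor (PSS = the seed-selection
video, PSSH = the storage-and-handling video) has exactly two treated and
two control units per block. One master seed drives matching and allocation
through deterministically derived sub-seeds, so a design is a pure function
of (baseline table, seed).

## Estimation

The estimand is a probability-point change in the share of correct answers.
`fit_block_fe_lpm()` fits, by OLS,

$$y_{t,b} = \alpha + \delta_b + \beta I_{t,b} + \varepsilon_{t,b}$$

with one block absorbed into the constant. The fixed effects are removed by
within-block demeaning (Frisch–Waugh) rather than a dummy-variable solve:
with dozens of blocks the demeaned regression is a one- or five-column
problem, numerically clean and cheap enough to re-fit thousands of times
inside the permutation loop. The dummy-variable `lm()` solve is retained in
the test suite as an independent oracle; the two agree to 1e-10 on
coefficients, block effects and residuals. With balanced quartets the slope
has a closed form — the across-block mean of within-block
treated-minus-control means — which is property-tested on random instances.

`fit_interaction_lpm()` adds two baseline knowledge flags and their
products with the indicator. The flags enter raw (uncentered 0/1), so the
indicator coefficient is the treatment effect among units with *no* prior
knowledge — that is the quantity the interaction table is read for.
Identically-zero regressor columns (e.g. interactions with an all-zero
flag) are dropped with `NA` coefficients, collapsing the model toward the
main-effect fit; any other exact collinearity is an error.

Neither fit computes standard errors. In samples of this size,
cluster-robust variance estimates are biased, and OLS asymptotics are wrong
for binary outcomes anyway; all uncertainty statements come from
randomization inference.

## Randomization inference

For either main effect, the randomization distribution is generated by the
six orderings of two T and two C within each quartet, independent across
quartets: `block_patterns()` returns
{TTCC, TCTC, TCCT, CCTT, CTTC, CTCT}, and `ri_pvalue()` either enumerates
all $6^B$ assignments exactly or samples M of them. Everything but the
indicator is held fixed across permutations; the statistic (by default the
block fixed-effects slope) is re-computed in full for every assignment — the
built-in statistics evaluate all permutations in one vectorized linear
solve that is property-tested identical to the one-at-a-time path.

Conventions, each an explicit choice:

* **p-value:** the raw proportion of permuted statistics at least as large
  as the observed one. No +1 correction is applied, so a reported p can be
  exactly 0 when the observed statistic beats every sampled permutation;
  the conservative (count+1)/(M+1) variant is available as
  `plus_one = TRUE` for users who need guaranteed validity.
* **Ties** count toward rejection (≥, not >) — conservative and standard.
* The observed assignment is **not injected** into the sampled set; the
  sample is M independent draws, nothing more.
* **Sidedness** is explicit in every result; the default is one-sided
  "greater", the direction of a hypothesized knowledge gain.
* **Exact-mode capacity:** exact enumeration is refused above B = 8 blocks
  (about 1.7 million assignments) with an error suggesting sampling; the
  bound is configurable.

### Calibration, discreteness, and why the 95% screen exists

Randomization p-values with the tie-inclusive convention are *valid but
conservative*: under the sharp null, P(p ≤ α) equals the largest achievable
level not exceeding α, which is strictly below α when the permutation
distribution is discrete. `run_calibration()` measures this directly —
simulating complete studies under the sharp null and tabulating per-cell
rejection rates and Kolmogorov–Smirnov uniformity checks. For outcomes with
base rates in the middle of the unit interval the slope's permutation
distribution is fine-grained and rejection rates sit just below nominal.
For near-degenerate outcomes — a question ~95% of units answer correctly —
the distribution collapses onto a handful of support points, p-values
become coarse and markedly super-uniform, and uniformity checks fail by
construction. This is not an estimator defect but the arithmetic of exact
tests on nearly-constant data, and it is precisely why the analysis
pre-registers the low-variation screen: `low_variation_flag()` marks any
outcome whose modal value covers ≥95% of observations (inclusive threshold,
computed on the full sample, invariant to relabeling 0↔1), and the
replication tables carry the flag rather than silently dropping the column.

## The synthetic generator

`generate_baseline()` draws nine covariates with marginals plausible for
smallholder potato-farming households (household size, head age and gender,
potato area, past extension contact, log yield, log welfare per capita,
distance to the nearest input dealer, credit access). Field studies of this
kind rarely publish their covariate marginals, so these are documented
stand-ins; the matching code accepts any complete numeric covariate set. An
optional latent-cluster knob creates separated covariate groups for
matching-quality tests.

`generate_outcomes()` is additive on the probability scale, mirroring the
linear-probability estimand so that generator parameters and estimates are
directly comparable: for each outcome,
p = base rate + direct effect + cross effect + knowledge shifts, then
Bernoulli. Defaults are calibration aids set near the magnitudes such a
study reports: control-group base rates (0.77, 0.89, 0.60, 0.95 for the
four video-covered questions; 0.55 and 0.50, chosen once as plausible, for
the two not-covered questions), a +0.28 direct storage-video effect on the
first storage question, cross-treatment spillovers of similar printed
magnitudes, knowledge prevalence 0.5 per flag with +0.05 main and −0.05
interaction shifts. Probabilities are clamped to [0.01, 0.99] — not [0, 1],
to keep simulated cells away from degeneracy that breaks group comparisons
at small n — and every clamping event is counted and logged. Knowledge
flags are independent of covariates by default; an association with
covariates, if wanted, must be introduced deliberately.

What the generator does *not* emulate: attrition, non-compliance,
spillovers between units, enumerator effects, or covariate-outcome
dependence. Passing tests therefore certify the design-and-inference
machinery under clean assignment mechanics, not robustness to those field
realities.

## Replication pipeline

`read_s1_csv()` reads the deposited-data dialect: first column the arm
label (`Sel+Store`, `Store`, `Sel`, `Ctrl`), six TRUE/FALSE outcome
columns, a block number, two TRUE/FALSE prior-knowledge flags. The actual
header names are supplied by a `column_map` with documented defaults, since
file headers vary; TRUE/FALSE in any case and 1/0 are the only accepted
binary encodings, anything else errors with the row named. Missing values
are rejected by default (the analysis assumes complete quiz responses); an
explicit `drop_incomplete = TRUE` drops and counts them, at the cost of
possibly partial quartets, which estimation then rejects.

`replicate_main()` produces one row per (outcome, effect) cell:
proportions, their difference, β̂, and the RI p-value, with provenance
(input hash, seeds, M, package version) attached. No multiple-testing
adjustment is applied — twelve unadjusted one-sided tests, the convention
this family of pre-registered analyses uses — and the printed table says
so; a Holm column is
available but off by default. `replicate_interactions()` follows a
configurable (outcome, effect) mapping, by default the three most-varying
outcomes crossed with featured and non-featured treatment, because the
published interaction-table layout does not pin down one regressor set per
column.

## Problem sizes and numerical tolerances

The test suite exercises the chain at the study's own scale where it
matters (248 units, 62 blocks) and at B = 2–15 blocks elsewhere; the
calibration experiment in the acceptance tests uses 500 simulated studies
at M = 2,000 permutations per cell, and the effect-recovery experiment 400
studies at the full n = 248. Identities (closed form vs demeaning vs dummy
solve; within-block residual sums) are asserted at 1e-10; permutation
tie detection uses a relative 1e-12 tolerance so that statistics computed
by the vectorized and scalar paths compare equal.

## Known limitations

* Greedy matching is order-dependent and makes no optimality claim.
* The linear probability model can fit probabilities outside [0, 1]; that
  is accepted for comparability with the difference in means, and no
  logistic alternative is offered.
* RI p-values are conservative in heavily tied cells (see above); users
  analyzing near-degenerate outcomes should heed the low-variation flag
  rather than the p-value.
* Exact enumeration is infeasible beyond a handful of blocks; sampled mode
  introduces Monte-Carlo error of order sqrt(p(1−p)/M).
* Interaction effects of the factorial itself (one cell vs another) are out
  of scope; with quartets the design is powered for main effects only.
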