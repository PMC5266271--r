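# Synthetic baseline and outcome generators.
#
# The generators emulate the two tables the design-and-inference chain
# consumes: a baseline covariate table for the matching stage and a binary
# quiz-outcome table in the deposited-data dialect for the inference stage.
# Outcome probabilities are additive on the probability scale (linear
# probability), so the generator's effect parameters are directly comparable
# to the linear-probability estimates that the analysis produces.

#' Baseline-generator configuration
#'
#' Settings for [generate_baseline()]: the number of units and an optional
#' latent cluster structure that shifts the continuous covariates, useful for
#' testing that matching recovers covariate similarity.
#'
#' @param n_units Number of units (default 248, at least 4).
#' @param clusters Optional number of latent covariate clusters.
#' @param cluster_sep Separation of cluster centres, in within-cluster
#'   standard deviations of the continuous covariates (0 = no structure).
#' @param seed Optional integer RNG seed.
#' @return A `baseline_config` list.
#' @export
baseline_config <- function(n_units = 248, clusters = NULL, cluster_sep = 0,
                            seed = NULL) {
  stopifnot(n_units >= 4)
  structure(list(n_units = as.integer(n_units), clusters = clusters,
                 cluster_sep = cluster_sep, seed = seed),
            class = "baseline_config")
}

#' Generate a synthetic baseline covariate table
#'
#' Draws a complete table of nine baseline characteristics per unit, with
#' marginal distributions plausible for smallholder potato-farming
#' households: household size (1 + Poisson), head age (bounded integer),
#' head gender (Bernoulli), potato area (log-normal, land units),
#' past potato extension (Bernoulli), log potato yield (Gaussian),
#' log welfare per capita (Gaussian), travel distance to the nearest input
#' dealer (Gamma, right-skewed) and credit access (Bernoulli). The covariate
#' schema is open: the matching stage accepts any complete numeric set.
#'
#' With a cluster structure configured, cluster-specific centre shifts of
#' size `cluster_sep` (in sd units) are added to the continuous covariates;
#' the latent labels are attached as attribute `"cluster"`.
#'
#' @param config A [baseline_config()].
#' @return Data.frame with `unit_id` and nine numeric covariate columns;
#'   attribute `"cluster"` holds the latent labels when clusters are drawn.
#' @export
generate_baseline <- function(config = baseline_config()) {
  stopifnot(inherits(config, "baseline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_units

  tab <- data.frame(
    unit_id = sprintf("u%03d", seq_len(n)),
    hh_size = 1 + stats::rpois(n, 5),
    head_age = pmin(pmax(round(stats::rnorm(n, 45, 14)), 18), 90),
    head_female = stats::rbinom(n, 1, 0.25),
    potato_area = stats::rlnorm(n, log(0.4), 0.8),
    past_extension = stats::rbinom(n, 1, 0.3),
    log_yield = stats::rnorm(n, 7.5, 0.8),
    log_welfare_pc = stats::rnorm(n, 13, 0.7),
    dist_dealer = stats::rgamma(n, shape = 2, scale = 3),
    credit_access = stats::rbinom(n, 1, 0.35),
    stringsAsFactors = FALSE
  )

  cluster <- NULL
  if (!is.null(config$clusters) && config$clusters > 1) {
    continuous <- c("hh_size", "head_age", "potato_area", "log_yield",
                    "log_welfare_pc", "dist_dealer")
    cluster <- sample.int(config$clusters, n, replace = TRUE)
    for (col in continuous) {
      s <- stats::sd(tab[[col]])
      centres <- stats::rnorm(config$clusters, 0, 1)
      centres <- centres - mean(centres)
      tab[[col]] <- tab[[col]] + config$cluster_sep * s * centres[cluster]
    }
  }
  attr(tab, "cluster") <- cluster
  tab
}

# default additive effect shifts (probability points); calibration aids set
# near the magnitudes the factorial design is built to detect
default_base_rate <- function() {
  c(sel1 = 0.77, sel2 = 0.89, store1 = 0.60, store2 = 0.95,
    gen1 = 0.55, gen2 = 0.50)
}

#' Outcome-generator configuration
#'
#' Effect structure for [generate_outcomes()]. Each unit's probability of
#' answering an outcome correctly is
#' `base_rate + direct + cross + knowledge shifts`, clamped to
#' `[0.01, 0.99]`:
#'
#' * `direct_effect[effect, outcome]` is added when the unit's arm includes
#'   `effect` and the outcome is one the corresponding video covers;
#' * `cross_effect[effect, outcome]` carries spillover of a treatment onto
#'   outcomes its video does not cover (the "general knowledge" channel) —
#'   both matrices are simply added for treated arms, the split is purely
#'   semantic;
#' * prior-knowledge flags are drawn Bernoulli(`know_prevalence`) and add
#'   `know_main` always and `know_by_treatment` when the matching treatment
#'   is received.
#'
#' Defaults put the direct effects near the magnitudes a factorial knowledge
#' experiment of this size is designed to detect (e.g. base rate 0.60 and a
#' +0.28 storage-video effect on the first storage question); zero matrices
#' give the sharp null.
#'
#' @param base_rate Named probability per outcome (control, no knowledge).
#' @param direct_effect,cross_effect 2 x 6 matrices (rows `PSS`, `PSSH`,
#'   columns the outcomes) of additive probability shifts applied when the
#'   unit received the row's treatment.
#' @param know_prevalence Probabilities of the two prior-knowledge flags,
#'   named `pss` and `pssh`.
#' @param know_main Additive shift per flag, applied to every outcome.
#' @param know_by_treatment Additive flag-by-matching-treatment interaction
#'   shift, applied to every outcome.
#' @param clamp Probability clamp bounds (default `c(0.01, 0.99)`).
#' @param seed Optional integer RNG seed.
#' @return An `effect_config` list.
#' @export
effect_config <- function(base_rate = default_base_rate(),
                          direct_effect = NULL,
                          cross_effect = NULL,
                          know_prevalence = c(pss = 0.5, pssh = 0.5),
                          know_main = c(pss = 0.05, pssh = 0.05),
                          know_by_treatment = c(pss = -0.05, pssh = -0.05),
                          clamp = c(0.01, 0.99),
                          seed = NULL) {
  zero <- matrix(0, 2, 6, dimnames = list(main_effects(), outcome_names()))
  if (is.null(direct_effect)) {
    direct_effect <- zero
    direct_effect["PSS", c("sel1", "sel2")] <- c(0.09, 0.07)
    direct_effect["PSSH", c("store1", "store2")] <- c(0.28, 0.02)
  }
  if (is.null(cross_effect)) {
    cross_effect <- zero
    cross_effect["PSS", c("store1", "store2", "gen1", "gen2")] <-
      c(0.28, 0.02, 0.13, 0.17)
    cross_effect["PSSH", c("sel1", "sel2", "gen1", "gen2")] <-
      c(0.07, 0.08, 0.08, 0.28)
  }
  stopifnot(
    setequal(names(base_rate), outcome_names()),
    identical(dim(direct_effect), c(2L, 6L)),
    identical(dim(cross_effect), c(2L, 6L)),
    all(is.finite(direct_effect)), all(is.finite(cross_effect)),
    length(clamp) == 2, clamp[1] < clamp[2]
  )
  structure(list(
    base_rate = base_rate[outcome_names()],
    direct_effect = direct_effect, cross_effect = cross_effect,
    know_prevalence = know_prevalence, know_main = know_main,
    know_by_treatment = know_by_treatment, clamp = clamp, seed = seed
  ), class = "effect_config")
}

#' Sharp-null outcome configuration
#'
#' An [effect_config()] with every treatment and knowledge shift set to zero:
#' outcomes depend on nothing but their base rates, so any test of a
#' treatment effect is testing a true sharp null.
#'
#' @param base_rate Named probability per outcome.
#' @param seed Optional integer RNG seed.
#' @return An `effect_config`.
#' @export
null_effect_config <- function(base_rate = default_base_rate(), seed = NULL) {
  zero <- matrix(0, 2, 6, dimnames = list(main_effects(), outcome_names()))
  effect_config(base_rate = base_rate, direct_effect = zero,
                cross_effect = zero,
                know_main = c(pss = 0, pssh = 0),
                know_by_treatment = c(pss = 0, pssh = 0),
                seed = seed)
}

#' Generate binary quiz outcomes for a designed study
#'
#' Draws the two prior-knowledge flags and the six binary outcomes for units
#' that already carry block ids and treatment arms. Each outcome is Bernoulli
#' with probability `base_rate + treatment shifts + knowledge shifts`,
#' clamped to the configured bounds; the number of clamped unit-outcome
#' probabilities is reported with a message and attached to the study's
#' metadata as `clamp_count`.
#'
#' @param units Data.frame with `unit_id`, `block_id` and `arm` (as produced
#'   by [design_study()]).
#' @param effects An [effect_config()].
#' @return A complete [quartet_study()].
#' @export
generate_outcomes <- function(units, effects = effect_config()) {
  stopifnot(is.data.frame(units), inherits(effects, "effect_config"))
  if (!"arm" %in% names(units) || any(is.na(units$arm))) {
    stop("units must have assigned arms")
  }
  if (!is.null(effects$seed)) set.seed(effects$seed)
  n <- nrow(units)
  i_pss <- main_effect_indicator(units$arm, "PSS")
  i_pssh <- main_effect_indicator(units$arm, "PSSH")

  know_pss <- stats::rbinom(n, 1, effects$know_prevalence[["pss"]])
  know_pssh <- stats::rbinom(n, 1, effects$know_prevalence[["pssh"]])

  shift <- function(eff_matrix) {
    outer(i_pss, eff_matrix["PSS", ]) + outer(i_pssh, eff_matrix["PSSH", ])
  }
  p <- matrix(effects$base_rate, n, 6, byrow = TRUE,
              dimnames = list(NULL, outcome_names())) +
    shift(effects$direct_effect) + shift(effects$cross_effect) +
    know_pss * effects$know_main[["pss"]] +
    know_pssh * effects$know_main[["pssh"]] +
    (know_pss * i_pss) * effects$know_by_treatment[["pss"]] +
    (know_pssh * i_pssh) * effects$know_by_treatment[["pssh"]]

  clamp_count <- sum(p < effects$clamp[1] | p > effects$clamp[2])
  if (clamp_count > 0) {
    message(clamp_count, " outcome probabilit",
            if (clamp_count == 1) "y" else "ies",
            " clamped to [", effects$clamp[1], ", ", effects$clamp[2], "]")
  }
  p <- pmin(pmax(p, effects$clamp[1]), effects$clamp[2])

  out <- units[c("unit_id", "block_id", "arm")]
  for (j in seq_along(outcome_names())) {
    out[[outcome_names()[j]]] <- stats::rbinom(n, 1, p[, j])
  }
  out$know_pss <- know_pss
  out$know_pssh <- know_pssh
  quartet_study(out, metadata = list(source = "synthetic",
                                     clamp_count = clamp_count))
}

#' Simulate a complete study end to end
#'
#' Baseline generation, greedy quartet matching, within-block factorial
#' allocation and outcome generation in one call, with sub-seeds for the
#' three stages derived deterministically from one master seed.
#'
#' @param n_units Number of units (default 248).
#' @param seed Optional master integer seed.
#' @param effects An [effect_config()].
#' @param baseline A [baseline_config()]; its `n_units` and `seed` are
#'   overridden by this function's arguments.
#' @param method Matching variant, see [form_blocks()].
#' @return A complete [quartet_study()]; the baseline table is kept in
#'   `$baseline`.
#' @export
simulate_study <- function(n_units = 248, seed = NULL,
                           effects = effect_config(),
                           baseline = baseline_config(n_units = n_units),
                           method = "seed_unit") {
  seeds <- derive_seeds(seed, 3L)
  baseline$n_units <- as.integer(n_units)
  baseline$seed <- seeds[[1]]
  base_tab <- generate_baseline(baseline)
  design <- design_study(base_tab, seed = seeds[[2]], method = method)
  effects$seed <- seeds[[3]]
  study <- generate_outcomes(design, effects)
  study$baseline <- base_tab
  study
}

#' Write a synthetic study in the deposited-data dialect
#'
#' Emits the study as a CSV with the treatment-arm label first, the six
#' outcomes and the two prior-knowledge flags as TRUE/FALSE, and the block
#' number — the dialect [read_s1_csv()] reads with its default column map.
#'
#' @param study A complete `quartet_study`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
emulate_s1 <- function(study, path) {
  write_s1_csv(study, path)
}
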