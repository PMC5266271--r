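# End-to-end orchestration: main-effect and interaction replication tables,
# the null-calibration experiment, and machine-readable report output.

#' Main-effect replication table
#'
#' For each of the six outcomes crossed with the two main-effect factors:
#' control and treated proportions, their difference, the block
#' fixed-effects LPM slope, and its one-sided randomization-inference
#' p-value. Outcomes caught by the pre-registered low-variation screen are
#' flagged — never silently dropped — so downstream readers can discard
#' them. No multiple-testing adjustment is applied (twelve unadjusted
#' one-sided tests); set `holm = TRUE` to add an optional Holm-adjusted
#' column.
#'
#' @param study A complete `quartet_study`.
#' @param M Permutations per randomization-inference p-value.
#' @param seed Optional master seed; per-cell sub-seeds are derived from it.
#' @param sidedness Passed to [ri_pvalue()].
#' @param holm Add a `p_holm` column (Holm over the twelve p-values).
#' @return A `report_table` data.frame, one row per (outcome, effect) cell,
#'   with provenance (seed, M, input source and hash, package version)
#'   attached as attribute `"provenance"`.
#' @export
replicate_main <- function(study, M = 10000, seed = NULL,
                           sidedness = "greater", holm = FALSE) {
  validate_study(study)
  u <- study$units
  cells <- expand.grid(outcome = outcome_names(), effect = main_effects(),
                       stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(cells))

  rows <- lapply(seq_len(nrow(cells)), function(i) {
    oc <- cells$outcome[i]
    ef <- cells$effect[i]
    ind <- main_effect_indicator(u$arm, ef)
    y <- u[[oc]]
    fit <- fit_block_fe_lpm(y, ind, u$block_id)
    ri <- ri_pvalue(study, oc, ef, statistic = "beta", M = M,
                    seed = seeds[[i]], sidedness = sidedness)
    data.frame(
      outcome = oc, effect = ef,
      prop_control = group_proportion(y, ind, "control"),
      prop_treated = group_proportion(y, ind, "treated"),
      diff_means = diff_in_means(y, ind),
      beta = fit$statistic,
      p_value = ri$p_value,
      n_permutations = ri$n_permutations,
      ri_mode = ri$mode,
      tie_count = ri$tie_count,
      low_variation = low_variation_flag(y),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  as_report_table(out, study, list(M = M, seed = seed, sidedness = sidedness,
                                   table = "main_effects"))
}

# default Table-3-style layout: the three outcomes with the most variation,
# each paired with its featured treatment and with the cross treatment
default_interaction_mapping <- function() {
  data.frame(
    outcome = c("sel1", "store1", "gen2", "gen2", "sel1", "store1"),
    effect = c("PSS", "PSSH", "PSS", "PSSH", "PSSH", "PSS"),
    stringsAsFactors = FALSE
  )
}

#' Prior-knowledge interaction replication table
#'
#' Fits [fit_interaction_lpm()] for each (outcome, effect) pair of the
#' mapping — by default the three most-varying outcomes, each paired with its
#' featured treatment and with the other treatment — and attaches a
#' randomization-inference p-value for the indicator coefficient (the effect
#' among units with both prior-knowledge flags zero). The statistic is
#' re-fitted in full for every permutation.
#'
#' @inheritParams replicate_main
#' @param mapping Data.frame with columns `outcome` and `effect`, one row per
#'   requested table column.
#' @return A `report_table` data.frame with the indicator coefficient
#'   (`beta`), the knowledge main-effect and interaction coefficients, and
#'   the indicator's RI p-value.
#' @export
replicate_interactions <- function(study, mapping = default_interaction_mapping(),
                                   M = 10000, seed = NULL,
                                   sidedness = "greater") {
  validate_study(study)
  u <- study$units
  stopifnot(all(c("know_pss", "know_pssh") %in% names(u)))
  seeds <- derive_seeds(seed, nrow(mapping))

  rows <- lapply(seq_len(nrow(mapping)), function(i) {
    oc <- mapping$outcome[i]
    ef <- mapping$effect[i]
    ind <- main_effect_indicator(u$arm, ef)
    y <- u[[oc]]
    fit <- fit_interaction_lpm(y, ind, u$know_pss, u$know_pssh, u$block_id)
    stat_fun <- function(s, indicator) {
      fit_interaction_lpm(s$units[[oc]], indicator, s$units$know_pss,
                          s$units$know_pssh, s$units$block_id)$statistic
    }
    ri <- ri_pvalue(study, oc, ef, statistic = stat_fun, M = M,
                    seed = seeds[[i]], sidedness = sidedness)
    data.frame(
      outcome = oc, effect = ef,
      beta = fit$statistic,
      know_pss = unname(fit$betas["know_pss"]),
      know_pssh = unname(fit$betas["know_pssh"]),
      know_pss_x = unname(fit$betas["know_pss_x_indicator"]),
      know_pssh_x = unname(fit$betas["know_pssh_x_indicator"]),
      p_value = ri$p_value,
      n_permutations = ri$n_permutations,
      low_variation = low_variation_flag(y),
      stringsAsFactors = FALSE
    )
  })
  as_report_table(do.call(rbind, rows), study,
                  list(M = M, seed = seed, sidedness = sidedness,
                       table = "interactions"))
}

as_report_table <- function(df, study, config) {
  src <- study$metadata$source %||% "unknown"
  hash <- if (is.character(src) && length(src) == 1 && file.exists(src)) {
    unname(tools::md5sum(src))
  } else {
    NA_character_
  }
  attr(df, "provenance") <- c(config, list(
    source = src, input_md5 = hash,
    n_units = n_units(study),
    n_blocks = length(unique(study$units$block_id)),
    package_version = as.character(utils::packageVersion("quartetri"))
  ))
  class(df) <- c("report_table", class(df))
  df
}

#' @export
print.report_table <- function(x, digits = 3, ...) {
  prov <- attr(x, "provenance")
  cat("replication table (", prov$table, "): ", prov$n_units, " units, ",
      prov$n_blocks, " blocks, M = ", prov$M, "\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  cat("note: p-values are unadjusted one-sided randomization-inference",
      "p-values;\ntwelve tests are reported without multiplicity",
      "correction.\n")
  invisible(x)
}

#' Write a replication report as JSON
#'
#' Serializes a `report_table` with its provenance block to a
#' machine-readable JSON file.
#'
#' @param report A `report_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "report_table"))
  payload <- list(provenance = attr(report, "provenance"),
                  table = as.data.frame(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Null-calibration experiment for the inference chain
#'
#' Simulates complete studies under the sharp null (or any supplied effect
#' configuration), runs the full design-and-inference chain on each, and
#' summarizes per-cell rejection rates with binomial 95% intervals and a
#' Kolmogorov-Smirnov uniformity check of the p-value distribution.
#' Rejection uses `p <= alpha`.
#'
#' @param n_replications Number of simulated studies.
#' @param alpha Nominal test level.
#' @param M Permutations per randomization-inference p-value.
#' @param seed Optional master seed; each replication gets a derived sub-seed.
#' @param n_units Units per simulated study.
#' @param effects An [effect_config()]; defaults to the sharp null.
#' @param cells Data.frame of (outcome, effect) cells to test; defaults to
#'   all twelve.
#' @return A `calibration_summary`: the replication-by-cell p-value matrix,
#'   a per-cell summary data.frame (rejection rate, binomial CI, KS statistic
#'   and p-value), and the pooled KS check.
#' @export
run_calibration <- function(n_replications = 500, alpha = 0.05, M = 2000,
                            seed = NULL, n_units = 248,
                            effects = null_effect_config(),
                            cells = expand.grid(outcome = outcome_names(),
                                                effect = main_effects(),
                                                stringsAsFactors = FALSE)) {
  seeds <- derive_seeds(seed, n_replications)
  p_mat <- matrix(NA_real_, n_replications, nrow(cells))
  colnames(p_mat) <- paste(cells$outcome, cells$effect, sep = ":")

  for (r in seq_len(n_replications)) {
    study <- simulate_study(n_units = n_units, seed = seeds[[r]],
                            effects = effects)
    # drop the first three derived values: simulate_study() consumed those
    # same sub-seeds for its baseline/design/outcome stages
    rep_seeds <- derive_seeds(seeds[[r]], nrow(cells) + 3L)[-(1:3)]
    for (i in seq_len(nrow(cells))) {
      p_mat[r, i] <- ri_pvalue(study, cells$outcome[i], cells$effect[i],
                               statistic = "beta", M = M,
                               seed = rep_seeds[[i]])$p_value
    }
  }

  ks_of <- function(p) {
    suppressWarnings(stats::ks.test(p, stats::punif))
  }
  summary_df <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    p <- p_mat[, i]
    rej <- mean(p <= alpha)
    ci <- stats::binom.test(sum(p <= alpha), length(p))$conf.int
    ks <- ks_of(p)
    data.frame(outcome = cells$outcome[i], effect = cells$effect[i],
               rejection_rate = rej, ci_lower = ci[1], ci_upper = ci[2],
               ks_stat = unname(ks$statistic), ks_p = ks$p.value,
               stringsAsFactors = FALSE)
  }))
  pooled <- ks_of(as.numeric(p_mat))

  structure(list(
    p_values = p_mat, cells = summary_df,
    pooled_ks_stat = unname(pooled$statistic), pooled_ks_p = pooled$p.value,
    alpha = alpha, n_replications = n_replications, M = M, seed = seed
  ), class = "calibration_summary")
}

#' @export
print.calibration_summary <- function(x, digits = 3, ...) {
  cat("null calibration:", x$n_replications, "replications, M =", x$M,
      ", alpha =", x$alpha, "\n")
  df <- x$cells
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  cat("pooled KS statistic:", round(x$pooled_ks_stat, digits),
      " (p =", signif(x$pooled_ks_p, 3), ")\n")
  invisible(x)
}
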