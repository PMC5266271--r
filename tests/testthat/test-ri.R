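# the within-block permutation null: pattern set, sampling, exact
# enumeration and p-value conventions

test_that("the six admissible patterns are exactly the 4-choose-2 labelings", {
  pat <- block_patterns()
  expect_equal(nrow(pat), 6L)
  expect_true(all(rowSums(pat) == 2L))
  expect_equal(rownames(pat), c("TTCC", "TCTC", "TCCT", "CCTT", "CTTC", "CTCT"))
  # combinatorial oracle: every way of placing two T among four positions
  brute <- t(apply(combn(4, 2), 2, function(ix) {
    v <- integer(4); v[ix] <- 1L; v
  }))
  key <- function(m) sort(unname(apply(m, 1, paste, collapse = "")))
  expect_identical(key(pat), key(brute))
})

test_that("permuted assignments keep two treated per block and are reproducible", {
  blocks <- rep(1:7, each = 4)
  ind <- permute_assignment(blocks, seed = 4)
  expect_equal(sum(ind), 14L)
  expect_true(all(tapply(ind, blocks, sum) == 2L))
  expect_identical(ind, permute_assignment(blocks, seed = 4))
  expect_error(permute_assignment(rep(1, 5)), "exactly 4 members")
})

test_that("each of the six patterns is drawn uniformly", {
  set.seed(9)
  pat <- block_patterns()
  n_draws <- 60000L
  draws <- vapply(seq_len(n_draws), function(i) permute_assignment(rep(1L, 4)),
                  integer(4))
  labels <- apply(draws, 2, paste, collapse = "")
  counts <- table(factor(labels, levels = apply(pat, 1, paste, collapse = "")))
  expect_true(all(counts > 0))
  expect_gt(chisq.test(counts)$p.value, 1e-4)
})

test_that("exact enumeration visits all 6^B assignments and matches a by-hand tally", {
  # B = 2: 36 assignments; oracle tallies the diff-in-means null directly
  study <- make_balanced_study(B = 2, seed = 12, p = 0.5)
  u <- study$units
  res <- ri_pvalue(study, "sel1", "PSS", statistic = "diff_means",
                   mode = "exact", keep_null = TRUE)
  expect_equal(res$n_permutations, 36L)
  pat <- block_patterns()
  oracle <- numeric(0)
  for (i in 1:6) for (j in 1:6) {
    ind <- c(pat[i, ], pat[j, ])
    oracle <- c(oracle, mean(u$sel1[ind == 1]) - mean(u$sel1[ind == 0]))
  }
  expect_equal(sort(res$null_dist), sort(oracle), tolerance = 1e-12)
  obs <- diff_in_means(u$sel1, main_effect_indicator(u$arm, "PSS"))
  expect_equal(res$observed_stat, obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(oracle >= obs - 1e-12))
})

test_that("the default p-value is the raw proportion and can reach zero", {
  # outcome equal to the PSS indicator: observed slope 1, every other
  # assignment scores strictly less; sampled draws that miss the observed
  # pattern give p = 0 under the no-plus-one convention
  study <- make_balanced_study(B = 4, seed = 1)
  u <- study$units
  u$sel1 <- main_effect_indicator(u$arm, "PSS")
  study <- quartet_study(u)
  res <- ri_pvalue(study, "sel1", "PSS", M = 150, seed = 8,
                   mode = "sampled", keep_null = TRUE)
  expect_equal(res$p_value, mean(res$null_dist >= res$observed_stat - 1e-12))
  expect_equal(res$observed_stat, 1)
  # the observed pattern has probability 6^-4 per draw; seed 8 misses it
  expect_equal(res$p_value, 0)
  # the conservative variant cannot be zero
  res1 <- ri_pvalue(study, "sel1", "PSS", M = 150, seed = 8,
                    mode = "sampled", plus_one = TRUE)
  expect_equal(res1$p_value, (res$n_extreme + 1) / (150 + 1))
  expect_gt(res1$p_value, 0)
})

test_that("exact mode refuses too many blocks and suggests sampling", {
  study <- make_balanced_study(B = 9, seed = 3)
  expect_error(ri_pvalue(study, "sel1", "PSS", mode = "exact"),
               "6\\^9.*sampled")
  # auto mode falls back to sampling
  res <- ri_pvalue(study, "sel1", "PSS", M = 200, seed = 1)
  expect_equal(res$mode, "sampled")
  expect_equal(res$n_permutations, 200L)
})

test_that("exact p-values are invariant to block ordering and member relabeling", {
  study <- make_balanced_study(B = 4, seed = 19, p = 0.5, effect = 0.3)
  p0 <- ri_pvalue(study, "sel1", "PSS", mode = "exact")$p_value

  # permute whole blocks and, within each block, the member rows
  set.seed(6)
  u <- study$units
  new_order <- unlist(lapply(sample(unique(u$block_id)), function(b) {
    sample(which(u$block_id == b))
  }))
  shuffled <- quartet_study(u[new_order, ])
  expect_equal(ri_pvalue(shuffled, "sel1", "PSS", mode = "exact")$p_value, p0)
})

test_that("one-sided p-values from both sides cover the null up to ties", {
  study <- make_balanced_study(B = 4, seed = 27, p = 0.6, effect = 0.2)
  g <- ri_pvalue(study, "store1", "PSSH", mode = "exact")
  l <- ri_pvalue(study, "store1", "PSSH", mode = "exact", sidedness = "less")
  expect_gte(g$p_value + l$p_value, 1)
  expect_equal(g$p_value + l$p_value - 1,
               g$tie_count / g$n_permutations, tolerance = 1e-12)
})

test_that("raising treated outcomes cannot lower the statistic or raise the p-value", {
  study <- make_balanced_study(B = 4, seed = 33, p = 0.4)
  u <- study$units
  ind <- main_effect_indicator(u$arm, "PSS")
  res0 <- ri_pvalue(study, "sel1", "PSS", statistic = "diff_means",
                    mode = "exact")
  u$sel1[ind == 1] <- 1L  # raise every treated outcome
  res1 <- ri_pvalue(quartet_study(u), "sel1", "PSS",
                    statistic = "diff_means", mode = "exact")
  expect_gte(res1$observed_stat, res0$observed_stat)
  expect_lte(res1$p_value, res0$p_value)
})

test_that("sampled p-values converge to the exact p-value as M grows", {
  study <- make_balanced_study(B = 5, seed = 41, p = 0.5, effect = 0.25)
  p_exact <- ri_pvalue(study, "sel1", "PSS", mode = "exact")$p_value
  for (M in c(100, 1000, 10000)) {
    p_s <- ri_pvalue(study, "sel1", "PSS", M = M, seed = 50,
                     mode = "sampled")$p_value
    expect_lt(abs(p_s - p_exact),
              3 * sqrt(p_exact * (1 - p_exact) / M) + 1e-12)
  }
})

test_that("a custom statistic function reproduces the built-in slope path", {
  study <- make_balanced_study(B = 4, seed = 52, p = 0.5, effect = 0.2)
  slow_stat <- function(s, indicator) {
    fit_block_fe_lpm(s$units$sel1, indicator, s$units$block_id)$statistic
  }
  fast <- ri_pvalue(study, "sel1", "PSS", statistic = "beta", mode = "exact",
                    keep_null = TRUE)
  slow <- ri_pvalue(study, "sel1", "PSS", statistic = slow_stat,
                    mode = "exact", keep_null = TRUE)
  expect_equal(slow$null_dist, fast$null_dist, tolerance = 1e-12)
  expect_equal(slow$p_value, fast$p_value)
  expect_equal(slow$observed_stat, fast$observed_stat, tolerance = 1e-12)
})

test_that("only the indicator moves across permutations", {
  study <- make_balanced_study(B = 3, seed = 61)
  seen <- new.env()
  seen$studies <- 0L
  probe <- function(s, indicator) {
    # the study object handed to the statistic is the original one
    if (identical(s, study)) seen$studies <- seen$studies + 1L
    mean(s$units$sel1[indicator == 1])
  }
  res <- ri_pvalue(study, "sel1", "PSS", statistic = probe, M = 25, seed = 5,
                   mode = "sampled")
  expect_gte(seen$studies, 25L)
  expect_equal(res$n_permutations, 25L)
})
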