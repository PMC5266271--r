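# Randomization inference over the within-block permutation null.
#
# Treatment was randomized within quartets, two treated and two control per
# block for either main effect, so the admissible re-assignments are the 6
# balanced patterns per block, independently across blocks: 6^B in total.
# p-values compare the observed statistic with its distribution over that
# set, enumerated exactly for few blocks or Monte-Carlo sampled otherwise.

#' The six admissible within-block assignment patterns
#'
#' All orderings of two treated (T) and two control (C) among the four
#' members of a quartet, in the conventional order
#' TTCC, TCTC, TCCT, CCTT, CTTC, CTCT.
#'
#' @return A 6 x 4 integer 0/1 matrix, one pattern per row (1 = treated),
#'   row names giving the T/C spelling.
#' @export
#' @examples
#' block_patterns()
block_patterns <- function() {
  pat <- rbind(
    TTCC = c(1L, 1L, 0L, 0L),
    TCTC = c(1L, 0L, 1L, 0L),
    TCCT = c(1L, 0L, 0L, 1L),
    CCTT = c(0L, 0L, 1L, 1L),
    CTTC = c(0L, 1L, 1L, 0L),
    CTCT = c(0L, 1L, 0L, 1L)
  )
  colnames(pat) <- paste0("pos", 1:4)
  pat
}

#' Draw one permuted within-block assignment
#'
#' Independently for each block, picks one of the six admissible patterns
#' uniformly at random and lays it over the block's members in their given
#' order. Everything else about the study (outcomes, covariates, knowledge
#' flags, block structure) is held fixed; only the indicator moves.
#'
#' @param blocks Vector of block labels, one per unit; each block must have
#'   exactly 4 members. Unit order within a block is the vector order.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (and advanced).
#' @return Integer 0/1 indicator vector, one per unit, with exactly two
#'   treated units per block.
#' @export
permute_assignment <- function(blocks, seed = NULL) {
  info <- block_structure(blocks)
  if (!is.null(seed)) set.seed(seed)
  draw_indicator_matrix(info, 1L)[, 1]
}

# positions and indices shared by the permutation machinery
block_structure <- function(blocks) {
  sizes <- table(blocks)
  if (any(sizes != 4L)) {
    stop("blocks without exactly 4 members: ",
         paste(names(sizes)[sizes != 4L], collapse = ", "))
  }
  f <- factor(blocks, levels = unique(blocks))
  block_index <- as.integer(f)
  pos <- stats::ave(seq_along(blocks), block_index, FUN = seq_along)
  list(n = length(blocks), n_blocks = nlevels(f),
       block_index = block_index, pos = as.integer(pos))
}

# indicator matrix (n x M) from an n_blocks x M matrix of pattern ids, or by
# sampling pattern ids uniformly when `dig` is NULL
draw_indicator_matrix <- function(info, M, dig = NULL) {
  if (is.null(dig)) {
    dig <- matrix(sample.int(6L, info$n_blocks * M, replace = TRUE),
                  info$n_blocks, M)
  }
  pat <- block_patterns()
  idx <- dig[info$block_index, , drop = FALSE]          # n x M pattern ids
  matrix(pat[(info$pos - 1L) * 6L + idx], info$n, M)
}

# all 6^B pattern-id combinations for columns first..last (1-based, as a
# B x k matrix); combination j has base-6 digits of (j-1)
enumerate_digits <- function(n_blocks, first, last) {
  j <- (first:last) - 1
  dig <- matrix(0L, n_blocks, length(j))
  for (b in seq_len(n_blocks)) {
    dig[b, ] <- as.integer((j %/% 6^(b - 1)) %% 6) + 1L
  }
  dig
}

# vectorized built-in statistics over an indicator matrix
ri_builtin_stat <- function(name, y, info) {
  y <- as.numeric(y)
  if (name == "beta") {
    function(ind) block_fe_slope(y, ind, info$block_index, info$n_blocks)
  } else if (name == "diff_means") {
    function(ind) {
      nt <- colSums(ind)
      as.numeric(colSums(y * ind) / nt - colSums(y * (1 - ind)) / (info$n - nt))
    }
  } else {
    stop("unknown built-in statistic '", name, "'")
  }
}

#' Randomization-inference p-value
#'
#' Computes the observed statistic under the study's actual assignment, then
#' its distribution over the within-block permutation null: exactly two
#' treated per quartet, independently across quartets. In `"exact"` mode all
#' `6^B` admissible assignments are enumerated (practical only for small B);
#' in `"sampled"` mode `M` assignments are drawn independently and uniformly.
#' The observed assignment is not forcibly injected into the sampled set.
#'
#' The default one-sided `"greater"` p-value is the raw proportion of
#' permuted statistics at least as large as the observed one (ties count
#' toward rejection); it can legitimately be 0. Set `plus_one = TRUE` for the
#' conservative `(count + 1) / (M + 1)` variant, which is guaranteed valid.
#'
#' @param study A `quartet_study` with arms, blocks and outcomes.
#' @param outcome Name of the outcome column the statistic uses.
#' @param effect Main-effect factor, `"PSS"` or `"PSSH"`, defining the
#'   observed indicator.
#' @param statistic `"beta"` (block fixed-effects LPM slope, the default),
#'   `"diff_means"`, or a function `f(study, indicator) -> numeric` evaluated
#'   in full for every permutation.
#' @param M Number of sampled permutations (ignored in exact mode).
#' @param seed Optional integer seed for the sampled permutations.
#' @param sidedness `"greater"` (default), `"less"` or `"two_sided"`.
#' @param mode `"auto"` (exact when `6^B <= max_exact`, else sampled),
#'   `"sampled"` or `"exact"`.
#' @param plus_one Use the conservative `(count + 1)/(M + 1)` convention.
#' @param max_exact_blocks Largest B for which exact mode is allowed
#'   (default 8, about 1.7 million assignments).
#' @param keep_null Store the full permuted-statistic vector in the result.
#' @return An `ri_result`: `observed_stat`, `p_value`, `n_permutations`,
#'   `mode`, `seed`, `sidedness`, `n_extreme` (assignments at least as
#'   extreme), `tie_count`, and optionally `null_dist`.
#' @export
ri_pvalue <- function(study, outcome, effect = c("PSS", "PSSH"),
                      statistic = "beta", M = 10000, seed = NULL,
                      sidedness = c("greater", "less", "two_sided"),
                      mode = c("auto", "sampled", "exact"),
                      plus_one = FALSE, max_exact_blocks = 8,
                      keep_null = FALSE) {
  effect <- match.arg(effect)
  sidedness <- match.arg(sidedness)
  mode <- match.arg(mode)
  stopifnot(inherits(study, "quartet_study"))
  u <- study$units
  if (!outcome %in% names(u)) stop("no outcome column '", outcome, "'")

  info <- block_structure(u$block_id)
  observed_ind <- main_effect_indicator(u$arm, effect)
  y <- as.numeric(u[[outcome]])

  if (is.function(statistic)) {
    eval_stat <- function(ind) {
      apply(ind, 2, function(col) statistic(study, as.integer(col)))
    }
    observed <- statistic(study, observed_ind)
  } else {
    eval_stat <- ri_builtin_stat(statistic, y, info)
    observed <- eval_stat(matrix(observed_ind, ncol = 1))
  }

  B <- info$n_blocks
  if (mode == "auto") {
    mode <- if (B <= max_exact_blocks) "exact" else "sampled"
  }
  if (mode == "exact" && B > max_exact_blocks) {
    stop("exact enumeration needs 6^", B, " assignments; ",
         "raise max_exact_blocks or use mode = \"sampled\"")
  }

  if (mode == "exact") {
    total <- 6^B
    chunk <- 50000L
    perm <- numeric(total)
    done <- 0L
    while (done < total) {
      k <- as.integer(min(chunk, total - done))
      dig <- enumerate_digits(B, done + 1L, done + k)
      perm[(done + 1L):(done + k)] <- eval_stat(draw_indicator_matrix(info, k, dig))
      done <- done + k
    }
    n_perm <- total
    seed_used <- NULL
  } else {
    if (!is.null(seed)) set.seed(seed)
    chunk <- 50000L
    perm <- numeric(M)
    done <- 0L
    while (done < M) {
      k <- as.integer(min(chunk, M - done))
      perm[(done + 1L):(done + k)] <- eval_stat(draw_indicator_matrix(info, k))
      done <- done + k
    }
    n_perm <- M
    seed_used <- seed
  }

  tol <- 1e-12 * max(1, abs(observed))
  ties <- sum(abs(perm - observed) <= tol)
  n_extreme <- switch(sidedness,
    greater = sum(perm >= observed - tol),
    less = sum(perm <= observed + tol),
    two_sided = sum(abs(perm) >= abs(observed) - tol)
  )
  p <- if (plus_one) (n_extreme + 1) / (n_perm + 1) else n_extreme / n_perm

  structure(list(
    observed_stat = observed,
    p_value = p,
    n_permutations = n_perm,
    mode = mode,
    seed = seed_used,
    sidedness = sidedness,
    plus_one = plus_one,
    n_extreme = n_extreme,
    tie_count = ties,
    null_dist = if (keep_null) perm else NULL,
    outcome = outcome,
    effect = effect,
    statistic = if (is.function(statistic)) "custom" else statistic
  ), class = "ri_result")
}

#' @export
print.ri_result <- function(x, digits = 4, ...) {
  cat("randomization inference (", x$mode, " mode, ",
      format(x$n_permutations, big.mark = ","), " permutations)\n", sep = "")
  cat("statistic [", x$statistic, "] ", x$effect, " on ", x$outcome, ": ",
      round(x$observed_stat, digits), "\n", sep = "")
  cat("one-sided (", x$sidedness, ") p = ", signif(x$p_value, 3),
      "  [", x$n_extreme, " of ", x$n_permutations, " as extreme, ",
      x$tie_count, " ties]\n", sep = "")
  invisible(x)
}
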