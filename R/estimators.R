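# Difference in means and block fixed-effects linear probability models.
#
# The block fixed effects are absorbed by within-block demeaning
# (Frisch-Waugh); the dummy-variable solve gives identical coefficients and
# is kept as a cross-check in the test suite. No standard errors are
# computed anywhere: inference is delegated entirely to randomization
# inference (ri_pvalue), which stays exact regardless of the regression
# specification.

#' Group proportion of a binary outcome
#'
#' Mean of a binary outcome over the treated or the control group defined by
#' a 0/1 indicator.
#'
#' @param outcome Binary 0/1 vector.
#' @param indicator Binary 0/1 treatment indicator, same length.
#' @param group `"treated"` (indicator 1) or `"control"` (indicator 0).
#' @return Proportion in `[0, 1]`.
#' @export
group_proportion <- function(outcome, indicator, group = c("treated", "control")) {
  group <- match.arg(group)
  if (length(outcome) != length(indicator)) {
    stop("outcome and indicator lengths differ")
  }
  sel <- indicator == (if (group == "treated") 1 else 0)
  if (!any(sel)) stop("empty ", group, " group")
  mean(outcome[sel])
}

#' Difference in means between treated and control
#'
#' The simple treated-minus-control comparison of proportions underlying the
#' bar-chart summaries of the factorial main effects.
#'
#' @inheritParams group_proportion
#' @return Treated mean minus control mean, in `[-1, 1]` for binary outcomes.
#' @export
diff_in_means <- function(outcome, indicator) {
  group_proportion(outcome, indicator, "treated") -
    group_proportion(outcome, indicator, "control")
}

# Core OLS with block fixed effects via within-block demeaning.
# X: numeric matrix of regressors (no intercept, no block dummies).
# Identically-zero raw columns are dropped with NA coefficients (they carry
# no information, e.g. interactions with an all-zero flag); any other rank
# deficiency is an error.
fit_block_fe <- function(y, X, block, statistic_name) {
  block <- as.factor(block)
  n <- length(y)
  stopifnot(nrow(X) == n, length(block) == n)

  zero_col <- colSums(abs(X)) == 0
  betas <- rep(NA_real_, ncol(X))
  names(betas) <- colnames(X)
  Xk <- X[, !zero_col, drop = FALSE]
  if (ncol(Xk) == 0) stop("no non-degenerate regressors")

  demean <- function(v) v - ave(v, block)
  yd <- demean(y)
  Xd <- apply(Xk, 2, demean)
  if (is.null(dim(Xd))) Xd <- matrix(Xd, ncol = ncol(Xk), dimnames = list(NULL, colnames(Xk)))

  fit <- stats::lm.fit(Xd, yd)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    stop("perfectly collinear regressors: ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "))
  }
  betas[!zero_col] <- coefs

  # recover intercept and block effects: mean(y|b) - mean(x|b) %*% beta gives
  # alpha + delta_b; the first block level is the reference (delta = 0)
  yb <- as.numeric(tapply(y, block, mean))
  xb <- apply(Xk, 2, function(v) tapply(v, block, mean))
  if (is.null(dim(xb))) xb <- matrix(xb, ncol = ncol(Xk))
  level_b <- as.numeric(yb - xb %*% coefs)
  alpha <- level_b[1]
  block_effects <- level_b[-1] - alpha
  names(block_effects) <- levels(block)[-1]

  fitted <- as.numeric(alpha + (level_b - alpha)[as.integer(block)] + Xk %*% coefs)
  residuals <- y - fitted

  structure(list(
    alpha = alpha,
    block_effects = block_effects,
    reference_block = levels(block)[1],
    betas = betas,
    residuals = residuals,
    fitted = fitted,
    n = n,
    statistic = unname(betas[statistic_name]),
    statistic_name = statistic_name
  ), class = "block_fe_fit")
}

#' @export
print.block_fe_fit <- function(x, digits = 4, ...) {
  cat("block fixed-effects LPM:", x$n, "units,",
      length(x$block_effects) + 1L, "blocks\n")
  cat("alpha:", round(x$alpha, digits), "\n")
  print(round(x$betas, digits))
  cat("statistic (", x$statistic_name, "): ",
      round(x$statistic, digits), "\n", sep = "")
  invisible(x)
}

#' Block fixed-effects linear probability model of a main effect
#'
#' Ordinary least squares of a binary outcome on the main-effect treatment
#' indicator plus block fixed effects (one block absorbed into the constant):
#' `y = alpha + delta_b + beta * I + eps`. With the factorial's balanced
#' quartets (2 treated, 2 control per block), the slope equals the
#' across-block average of the within-block treated-minus-control means.
#' The slope is the fit's `statistic`, targeted by randomization inference.
#'
#' @param outcome Binary 0/1 outcome vector.
#' @param indicator Binary 0/1 main-effect treatment indicator.
#' @param blocks Block labels, one per unit; each block must contain exactly
#'   2 treated and 2 control units.
#' @return A `block_fe_fit`: intercept `alpha`, named `block_effects`
#'   (reference absorbed), `betas`, `residuals`, `fitted`, `n`, `statistic`.
#' @export
fit_block_fe_lpm <- function(outcome, indicator, blocks) {
  check_balanced_blocks(indicator, blocks)
  X <- matrix(as.numeric(indicator), ncol = 1,
              dimnames = list(NULL, "indicator"))
  fit_block_fe(as.numeric(outcome), X, blocks, "indicator")
}

check_balanced_blocks <- function(indicator, blocks) {
  if (length(indicator) != length(blocks)) {
    stop("indicator and blocks lengths differ")
  }
  if (!all(indicator %in% c(0, 1))) stop("indicator must be 0/1")
  tr <- tapply(indicator, blocks, sum)
  sz <- tapply(indicator, blocks, length)
  bad <- names(tr)[sz != 4L | tr != 2L]
  if (length(bad)) {
    stop("blocks without 2 treated / 2 control in 4 members: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Prior-knowledge interaction linear probability model
#'
#' OLS of a binary outcome on the main-effect indicator, the two
#' prior-knowledge flags, their interactions with the indicator, and block
#' fixed effects plus a constant:
#' `y = alpha + delta_b + beta*I + g1*K_pss + g2*K_pssh + h1*K_pss*I +
#' h2*K_pssh*I + eps`. The knowledge flags enter raw (uncentered 0/1), so the
#' indicator coefficient — the fit's `statistic` — is the treatment effect
#' among units with both flags equal to zero.
#'
#' Identically-zero regressor columns (e.g. an interaction with an all-zero
#' flag) are dropped and reported as `NA`, in which case the model reduces
#' toward [fit_block_fe_lpm()]; any other exact collinearity is an error.
#'
#' @inheritParams fit_block_fe_lpm
#' @param know_pss,know_pssh Binary 0/1 prior-knowledge flags.
#' @return A `block_fe_fit` with `betas` named `indicator`, `know_pss`,
#'   `know_pssh`, `know_pss_x_indicator`, `know_pssh_x_indicator`.
#' @export
fit_interaction_lpm <- function(outcome, indicator, know_pss, know_pssh, blocks) {
  check_balanced_blocks(indicator, blocks)
  stopifnot(all(know_pss %in% c(0, 1)), all(know_pssh %in% c(0, 1)))
  X <- cbind(
    indicator = as.numeric(indicator),
    know_pss = as.numeric(know_pss),
    know_pssh = as.numeric(know_pssh),
    know_pss_x_indicator = as.numeric(know_pss * indicator),
    know_pssh_x_indicator = as.numeric(know_pssh * indicator)
  )
  fit_block_fe(as.numeric(outcome), X, blocks, "indicator")
}

# Fast slope-only evaluation of the block-FE LPM for one or many indicator
# columns at once. Exactly the Frisch-Waugh solve of fit_block_fe_lpm
# restricted to the slope; used by the vectorized randomization-inference
# path and property-tested against fit_block_fe_lpm.
block_fe_slope <- function(y, X, block_index, n_blocks) {
  X <- as.matrix(X)
  yd <- y - rowsum_expand(y, block_index, n_blocks)
  Xbar <- apply_rowsum_expand(X, block_index, n_blocks)
  Xd <- X - Xbar
  as.numeric(colSums(Xd * yd) / colSums(Xd * Xd))
}

rowsum_expand <- function(v, block_index, n_blocks) {
  m <- rowsum(v, block_index, reorder = TRUE) / 4
  m[block_index, 1]
}

apply_rowsum_expand <- function(X, block_index, n_blocks) {
  m <- rowsum(X, block_index, reorder = TRUE) / 4
  m[block_index, , drop = FALSE]
}
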