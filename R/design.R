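# Ex-ante matched quartet blocking and factorial arm allocation.

#' Standardize a baseline covariate table
#'
#' Centers every covariate by its sample mean and scales by its sample
#' standard deviation (n-1 denominator), so all characteristics receive equal
#' weight in the matching distance. Binary covariates are standardized exactly
#' like continuous ones. Constant columns map to all-zero columns rather than
#' dividing by zero. Location and scale are computed once, on the full
#' pre-matching sample.
#'
#' @param covariate_table Data.frame or matrix of complete numeric covariates,
#'   one row per unit; binaries coded 0/1. Row names (or a `unit_id` column,
#'   which is set aside) identify units.
#' @return An object of class `standardized_covariates`: list with `z` (the
#'   standardized matrix), `center` and `scale` (per-covariate statistics
#'   used; scale is reported as 0 for constant columns).
#' @export
standardize_covariates <- function(covariate_table) {
  tab <- covariate_table
  if (is.data.frame(tab) && "unit_id" %in% names(tab)) {
    rn <- as.character(tab$unit_id)
    tab <- tab[setdiff(names(tab), "unit_id")]
    rownames(tab) <- rn
  }
  x <- as.matrix(tab)
  if (!is.numeric(x)) stop("covariates must be numeric")
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("missing covariate value: unit '",
         rownames(x)[idx[1]] %||% idx[1], "', covariate '",
         colnames(x)[idx[2]] %||% idx[2], "'")
  }
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  z <- sweep(x, 2, center, "-")
  nonconst <- scale > 0
  z[, nonconst] <- sweep(z[, nonconst, drop = FALSE], 2, scale[nonconst], "/")
  z[, !nonconst] <- 0
  structure(list(z = z, center = center, scale = ifelse(nonconst, scale, 0)),
            class = "standardized_covariates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.standardized_covariates <- function(x, ...) {
  cat("standardized_covariates:", nrow(x$z), "units,", ncol(x$z),
      "covariates (", sum(x$scale == 0), "constant )\n")
  invisible(x)
}

#' Matching distance between two units
#'
#' The square root of the sum of squared standardized differences — the
#' Euclidean distance on the standardized covariate scale, with every
#' characteristic weighted equally.
#'
#' @param u,v Equal-length numeric vectors of standardized covariates from the
#'   same standardization.
#' @return Nonnegative scalar distance.
#' @export
#' @examples
#' pair_distance(c(0, 0), c(1, 0))  # 1
pair_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("length mismatch: ", length(u), " vs ", length(v))
  }
  sqrt(sum((u - v)^2))
}

#' Greedy quartet matching
#'
#' Partitions units into blocks of four by the greedy seed-unit procedure:
#' draw one unit uniformly at random from the remaining pool, attach the
#' remaining unit nearest to that seed unit (matching distance on
#' standardized covariates) three successive times, give the quartet the next
#' block number, remove it from the pool, and repeat until the pool is
#' exhausted. Deterministic given `seed`. Nearest-neighbour ties are broken by
#' the lexicographically smallest unit id.
#'
#' If the unit count is not divisible by four, the final `r < 4` leftover
#' units are excluded from the design with a warning naming them.
#'
#' @param baseline Data.frame with a `unit_id` column and numeric covariate
#'   columns, or a `standardized_covariates` object.
#' @param seed Integer RNG seed governing the random draw order.
#' @param method `"seed_unit"` (default): members 2-4 are each nearest to the
#'   original seed unit. `"centroid"`: each new member is nearest to the mean
#'   of the standardized covariates of the members chosen so far.
#' @return Data.frame with columns `unit_id` and `block_id` (integer, 1-based
#'   in emission order), one row per matched unit. Leftover unit ids, if any,
#'   are attached as attribute `"leftover"`.
#' @export
form_blocks <- function(baseline, seed = NULL,
                        method = c("seed_unit", "centroid")) {
  method <- match.arg(method)
  if (inherits(baseline, "standardized_covariates")) {
    z <- baseline$z
  } else {
    z <- standardize_covariates(baseline)$z
  }
  n <- nrow(z)
  if (n < 4) stop("need at least 4 units to form a block")
  ids <- rownames(z) %||% as.character(seq_len(n))
  rownames(z) <- ids

  leftover_n <- n %% 4L
  if (!is.null(seed)) set.seed(seed)

  # full pairwise distance matrix once; pool shrinks by index
  d <- as.matrix(stats::dist(z, method = "euclidean"))
  pool <- seq_len(n)
  n_blocks <- n %/% 4L
  block_of <- integer(n)

  for (b in seq_len(n_blocks)) {
    anchor <- pool[sample.int(length(pool), 1L)]
    members <- anchor
    pool <- setdiff(pool, anchor)
    for (k in 1:3) {
      if (method == "seed_unit") {
        dd <- d[anchor, pool]
      } else {
        centroid <- colMeans(z[members, , drop = FALSE])
        dd <- sqrt(colSums((t(z[pool, , drop = FALSE]) - centroid)^2))
      }
      # ties: smallest distance, then lexicographically smallest unit id
      best <- pool[dd == min(dd)]
      pick <- best[order(ids[best])][1]
      members <- c(members, pick)
      pool <- setdiff(pool, pick)
    }
    block_of[members] <- b
  }

  if (leftover_n > 0) {
    warning(leftover_n, " leftover unit(s) excluded from the design: ",
            paste(ids[pool], collapse = ", "))
  }
  matched <- which(block_of > 0)
  out <- data.frame(unit_id = ids[matched], block_id = block_of[matched],
                    stringsAsFactors = FALSE)
  out <- out[order(out$block_id, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "leftover") <- ids[pool]
  out
}

#' Random within-block allocation of the four factorial arms
#'
#' Independently in each quartet, assigns the four arms (`Ctrl`, `Sel`,
#' `Store`, `Sel+Store`) to the four members by a uniformly random
#' permutation. Deterministic given `seed`.
#'
#' @param blocks Data.frame with columns `unit_id` and `block_id`, every block
#'   of size exactly 4 (as produced by [form_blocks()]).
#' @param seed Integer RNG seed.
#' @return The input data.frame with an added `arm` column.
#' @export
assign_arms <- function(blocks, seed = NULL) {
  stopifnot(is.data.frame(blocks), all(c("unit_id", "block_id") %in% names(blocks)))
  sizes <- table(blocks$block_id)
  if (any(sizes != 4L)) {
    stop("blocks without exactly 4 members: ",
         paste(names(sizes)[sizes != 4L], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  arms <- arm_levels()
  out <- blocks
  out$arm <- NA_character_
  for (b in unique(out$block_id)) {
    rows <- which(out$block_id == b)
    out$arm[rows] <- arms[sample.int(4L)]
  }
  out
}

#' Run the full design stage
#'
#' Convenience wrapper: standardize the baseline covariates, form quartets by
#' greedy matching, and allocate the factorial arms within each quartet. Two
#' independent sub-seeds, derived deterministically from `seed`, govern the
#' matching draw order and the arm permutations.
#'
#' @param baseline Data.frame with `unit_id` and numeric covariate columns.
#' @param seed Integer RNG seed for the whole design stage.
#' @param method Matching variant passed to [form_blocks()].
#' @return Data.frame with columns `unit_id`, `block_id`, `arm`.
#' @export
design_study <- function(baseline, seed = NULL, method = "seed_unit") {
  seeds <- derive_seeds(seed, 2L)
  blocks <- form_blocks(baseline, seed = seeds[[1]], method = method)
  assign_arms(blocks, seed = seeds[[2]])
}

# deterministic sub-seeds below 2^31 from one master seed
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}
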