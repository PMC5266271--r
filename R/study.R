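# Study container, treatment-arm vocabulary, outcome-file I/O and the
# low-variation outcome screen.

#' Canonical treatment-arm labels
#'
#' The four conditions of the 2x2 factorial: control, seed-selection video
#' only, storage-and-handling video only, and both videos. The labels are the
#' ones used in the deposited outcome file: `"Ctrl"`, `"Sel"`, `"Store"`,
#' `"Sel+Store"`.
#'
#' @return Character vector of the four arm labels, in canonical order.
#' @export
#' @examples
#' arm_levels()
arm_levels <- function() {
  c("Ctrl", "Sel", "Store", "Sel+Store")
}

#' Main-effect factor names
#'
#' The two factors of the factorial: `"PSS"` (positive seed selection) and
#' `"PSSH"` (proper seed storage and handling). A unit is treated on PSS if
#' its arm is `Sel` or `Sel+Store`, and treated on PSSH if its arm is `Store`
#' or `Sel+Store`.
#'
#' @return Character vector `c("PSS", "PSSH")`.
#' @export
main_effects <- function() {
  c("PSS", "PSSH")
}

#' Quiz outcome variable names
#'
#' The six binary quiz outcomes: two on seed selection (`sel1`, `sel2`), two
#' on storage and handling (`store1`, `store2`) and two on related topics not
#' covered explicitly by either video (`gen1`, `gen2`).
#'
#' @return Character vector of the six outcome names.
#' @export
outcome_names <- function() {
  c("sel1", "sel2", "store1", "store2", "gen1", "gen2")
}

#' Main-effect treatment indicator
#'
#' Maps a treatment arm to the 0/1 indicator of a main-effect factor: `I = 1`
#' iff the arm includes that factor's video.
#'
#' @param arm Character vector of arm labels (see [arm_levels()]).
#' @param effect One of `"PSS"` or `"PSSH"`.
#' @return Integer vector of 0/1 indicators, same length as `arm`.
#' @export
#' @examples
#' main_effect_indicator(c("Ctrl", "Sel", "Store", "Sel+Store"), "PSS")
main_effect_indicator <- function(arm, effect = c("PSS", "PSSH")) {
  effect <- match.arg(effect)
  bad <- !is.na(arm) & !(arm %in% arm_levels())
  if (any(bad)) {
    stop("unknown arm label(s): ", paste(unique(arm[bad]), collapse = ", "))
  }
  treated <- if (effect == "PSS") c("Sel", "Sel+Store") else c("Store", "Sel+Store")
  as.integer(arm %in% treated)
}

#' Default column mapping for the outcome-file dialect
#'
#' Names of the columns expected in an outcome CSV: the treatment arm, the six
#' quiz outcomes, the block number, and the two prior-knowledge flags. Override
#' entries to read files that use different headers.
#'
#' @param ... Named overrides, e.g. `arm = "treat"`.
#' @return Named list with entries `arm`, `sel1` ... `gen2`, `block`,
#'   `know_pss`, `know_pssh`.
#' @export
s1_column_map <- function(...) {
  map <- list(
    arm = "treatment",
    sel1 = "sel1", sel2 = "sel2",
    store1 = "store1", store2 = "store2",
    gen1 = "gen1", gen2 = "gen2",
    block = "block",
    know_pss = "know_sel",
    know_pssh = "know_store"
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(map))
    if (length(unknown)) {
      stop("unknown column_map entries: ", paste(unknown, collapse = ", "))
    }
    map[names(dots)] <- dots
  }
  map
}

#' Construct a quartet study
#'
#' Bundles per-unit records into the container used by the estimation and
#' inference functions. Units carry an identifier, optionally a block id and a
#' treatment arm, the six binary outcomes and two binary prior-knowledge flags.
#'
#' @param units A data.frame with columns `unit_id`, optionally `arm` (labels
#'   from [arm_levels()]), `block_id`, the six outcomes from
#'   [outcome_names()] coded 0/1, and `know_pss`, `know_pssh` coded 0/1.
#' @param metadata Optional list of provenance fields (source label, column
#'   map used, ...).
#' @param validate Check the block/arm invariants (default `TRUE`).
#' @return An object of class `quartet_study`.
#' @export
quartet_study <- function(units, metadata = list(), validate = TRUE) {
  stopifnot(is.data.frame(units))
  if (!"unit_id" %in% names(units)) {
    units$unit_id <- as.character(seq_len(nrow(units)))
  }
  units$unit_id <- as.character(units$unit_id)
  study <- structure(
    list(units = as.data.frame(units, stringsAsFactors = FALSE),
         metadata = metadata),
    class = "quartet_study"
  )
  if (validate) validate_study(study)
  study
}

#' Validate a quartet study
#'
#' Checks the container invariants: unit ids unique; outcomes and
#' prior-knowledge flags, when present, are 0/1; every block, when block ids
#' are present, has exactly four members; when arms are assigned, each block
#' holds each of the four arms exactly once.
#'
#' @param study A `quartet_study`.
#' @return `study`, invisibly; errors describe every violation found.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "quartet_study"))
  u <- study$units
  if (anyDuplicated(u$unit_id)) {
    stop("duplicated unit_id values")
  }
  for (col in c(outcome_names(), "know_pss", "know_pssh")) {
    if (col %in% names(u)) {
      vals <- u[[col]]
      if (any(is.na(vals)) || !all(vals %in% c(0L, 1L))) {
        stop("column '", col, "' must be binary 0/1 with no missing values")
      }
    }
  }
  if ("arm" %in% names(u)) {
    bad <- !is.na(u$arm) & !(u$arm %in% arm_levels())
    if (any(bad)) {
      stop("unknown arm label(s): ", paste(unique(u$arm[bad]), collapse = ", "))
    }
  }
  if ("block_id" %in% names(u) && !all(is.na(u$block_id))) {
    sizes <- table(u$block_id)
    off <- names(sizes)[sizes != 4L]
    if (length(off)) {
      stop("blocks without exactly 4 members: ", paste(off, collapse = ", "))
    }
    if ("arm" %in% names(u) && !any(is.na(u$arm))) {
      by_block <- split(u$arm, u$block_id)
      bad <- names(by_block)[!vapply(by_block, function(a) {
        setequal(a, arm_levels()) && !anyDuplicated(a)
      }, logical(1))]
      if (length(bad)) {
        stop("blocks where the four arms do not each appear once: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  invisible(study)
}

#' @export
print.quartet_study <- function(x, ...) {
  u <- x$units
  n_blocks <- if ("block_id" %in% names(u)) length(unique(u$block_id)) else 0L
  cat("quartet_study:", nrow(u), "units,", n_blocks, "blocks\n")
  if ("arm" %in% names(u) && !all(is.na(u$arm))) {
    cat("arms:", paste(sprintf("%s=%d", names(table(u$arm)), table(u$arm)),
                       collapse = " "), "\n")
  }
  present <- intersect(outcome_names(), names(u))
  if (length(present)) cat("outcomes:", paste(present, collapse = " "), "\n")
  invisible(x)
}

#' Number of units in a study
#' @param study A `quartet_study`.
#' @return Integer count of units.
#' @export
n_units <- function(study) {
  stopifnot(inherits(study, "quartet_study"))
  nrow(study$units)
}

#' Block membership of a study
#'
#' @param study A `quartet_study` with block ids.
#' @return Named list mapping each block id to the integer row indices of its
#'   members, in row order.
#' @export
study_blocks <- function(study) {
  stopifnot(inherits(study, "quartet_study"))
  u <- study$units
  if (!"block_id" %in% names(u) || all(is.na(u$block_id))) {
    stop("study has no block ids")
  }
  split(seq_len(nrow(u)), u$block_id)
}

# parse one raw CSV column of TRUE/FALSE (any case) or 1/0 into integer 0/1
parse_binary_column <- function(x, col) {
  raw <- trimws(as.character(x))
  up <- toupper(raw)
  out <- rep(NA_integer_, length(raw))
  out[up %in% c("TRUE", "1")] <- 1L
  out[up %in% c("FALSE", "0")] <- 0L
  bad <- which(is.na(out) & !is.na(raw) & nzchar(raw))
  if (length(bad)) {
    stop("column '", col, "': unparseable binary value '", raw[bad[1]],
         "' at row ", bad[1],
         " (accepted encodings: TRUE/FALSE any case, 1/0)")
  }
  out
}

#' Read an outcome CSV in the deposited-data dialect
#'
#' Reads a delimited text file with one row per unit: a treatment-arm column
#' with labels `Ctrl` / `Sel` / `Store` / `Sel+Store`, six TRUE/FALSE quiz
#' outcome columns, a block-number column and two TRUE/FALSE prior-knowledge
#' flags. TRUE/FALSE in any case and 1/0 are accepted as binary encodings;
#' anything else is an error, never silently coerced.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Mapping from the roles to the file's column names; see
#'   [s1_column_map()].
#' @param sep Field separator (default comma).
#' @param drop_incomplete If `TRUE`, rows with missing outcome or flag values
#'   are dropped with a message stating how many; the default (`FALSE`)
#'   rejects them, since the analysis assumes complete quiz responses.
#' @return A [quartet_study()].
#' @export
read_s1_csv <- function(path, column_map = s1_column_map(), sep = ",",
                        drop_incomplete = FALSE) {
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  needed <- unlist(column_map, use.names = FALSE)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) not found in file: ",
         paste(missing_cols, collapse = ", "))
  }

  arm <- trimws(as.character(raw[[column_map$arm]]))
  bad <- which(!(arm %in% arm_levels()))
  if (length(bad)) {
    stop("unknown arm label '", arm[bad[1]], "' at row ", bad[1])
  }

  bin_roles <- c(outcome_names(), "know_pss", "know_pssh")
  units <- data.frame(unit_id = as.character(seq_len(nrow(raw))),
                      arm = arm, stringsAsFactors = FALSE)
  units$block_id <- raw[[column_map$block]]
  for (role in bin_roles) {
    units[[role]] <- parse_binary_column(raw[[column_map[[role]]]], column_map[[role]])
  }

  incomplete <- rowSums(is.na(units[bin_roles])) > 0
  dropped <- FALSE
  if (any(incomplete)) {
    if (drop_incomplete) {
      message("dropping ", sum(incomplete), " row(s) with missing binary values")
      units <- units[!incomplete, , drop = FALSE]
      dropped <- TRUE
    } else {
      stop(sum(incomplete), " row(s) have missing binary values ",
           "(first at row ", which(incomplete)[1], "); ",
           "use drop_incomplete = TRUE to drop them")
    }
  }

  # dropping rows can leave partial quartets, so the block-structure
  # invariants are not enforced here; estimation re-checks balance
  quartet_study(units,
                metadata = list(source = path, column_map = column_map,
                                dropped_incomplete = sum(incomplete)),
                validate = !dropped)
}

#' Write a study in the outcome-CSV dialect
#'
#' Emits the same dialect [read_s1_csv()] reads: arm label first, then the six
#' outcomes as TRUE/FALSE, the block number, and the two prior-knowledge flags
#' as TRUE/FALSE. `write_s1_csv(read_s1_csv(f))` round-trips content exactly.
#'
#' @param study A complete `quartet_study` (arms, blocks, outcomes, flags).
#' @param path Output file path.
#' @param column_map Column names to write; see [s1_column_map()].
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_s1_csv <- function(study, path, column_map = s1_column_map(), sep = ",") {
  stopifnot(inherits(study, "quartet_study"))
  u <- study$units
  need <- c("arm", outcome_names(), "block_id", "know_pss", "know_pssh")
  missing_fields <- setdiff(need, names(u))
  if (length(missing_fields) || any(is.na(u[need]))) {
    stop("study is incomplete; cannot write: ",
         paste(missing_fields, collapse = ", "))
  }
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL,
                    arm = u$arm)
  names(out) <- column_map$arm
  for (role in outcome_names()) {
    out[[column_map[[role]]]] <- u[[role]] == 1L
  }
  out[[column_map$block]] <- u$block_id
  out[[column_map$know_pss]] <- u$know_pss == 1L
  out[[column_map$know_pssh]] <- u$know_pssh == 1L
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Low-variation outcome screen
#'
#' Flags a binary outcome whose modal value covers at least `threshold` of
#' observations. Such outcomes carry almost no information and, per the
#' pre-registered rule this implements, are discarded from the analysis. The
#' share is computed on the full sample and the comparison is inclusive
#' (exactly 95% of identical values is flagged at the default threshold).
#'
#' @param outcome_values Nonempty vector of 0/1 values.
#' @param threshold Modal share at or above which the outcome is flagged
#'   (default 0.95).
#' @return `TRUE` if the modal share is `>= threshold`, else `FALSE`.
#' @export
#' @examples
#' low_variation_flag(c(rep(1, 96), rep(0, 4)))  # TRUE
#' low_variation_flag(rep(0:1, 50))              # FALSE
low_variation_flag <- function(outcome_values, threshold = 0.95) {
  if (length(outcome_values) == 0) {
    stop("outcome_values must be nonempty")
  }
  if (any(is.na(outcome_values)) || !all(outcome_values %in% c(0, 1))) {
    stop("outcome_values must be 0/1 with no missing values")
  }
  share_one <- mean(outcome_values == 1)
  max(share_one, 1 - share_one) >= threshold
}
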