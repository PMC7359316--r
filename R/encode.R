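#' One-hot encode trial records against a feature space
#'
#' Builds the n-by-p binary design matrix with exactly one 1 per block per
#' row (six ones per row), plus the yield response vector. Labels absent from
#' the feature space raise an error rather than silently extending the space.
#'
#' @param records A trial-record tibble (usually after
#'   [aggregate_replicates()]).
#' @param fs A `feature_space` from [build_feature_space()].
#' @return A list with `X` (n-by-p binary matrix with `block=label` column
#'   names), `y` (yield vector), and `keys` (per-row combination identifier).
#' @export
encode_records <- function(records, fs) {
  records <- validate_records(records)
  stopifnot(inherits(fs, "feature_space"))
  n <- nrow(records)
  offsets <- c(0, cumsum(lengths(fs$blocks)))
  X <- matrix(0, nrow = n, ncol = fs$p,
              dimnames = list(NULL, feature_names(fs)))
  for (bi in seq_along(BLOCK_NAMES)) {
    b <- BLOCK_NAMES[bi]
    idx <- match(records[[b]], fs$blocks[[b]])
    if (anyNA(idx)) {
      bad <- unique(records[[b]][is.na(idx)])
      abort(paste0("label(s) not in feature space block '", b, "': ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    X[cbind(seq_len(n), offsets[bi] + idx)] <- 1
  }
  keys <- do.call(paste, c(records[BLOCK_NAMES], sep = "|"))
  list(X = X, y = records$yield, keys = keys)
}

#' Decode a one-hot design matrix back to label columns
#'
#' Inverse of [encode_records()] for roster-mode matrices: recovers the six
#' label columns from the position of the 1 in each block.
#'
#' @param X A binary design matrix produced by [encode_records()].
#' @param fs The `feature_space` used to encode it.
#' @return A tibble with the six label columns.
#' @export
decode_design <- function(X, fs) {
  stopifnot(inherits(fs, "feature_space"), ncol(X) == fs$p)
  offsets <- c(0, cumsum(lengths(fs$blocks)))
  out <- lapply(seq_along(BLOCK_NAMES), function(bi) {
    sub <- X[, (offsets[bi] + 1):offsets[bi + 1], drop = FALSE]
    hit <- max.col(sub, ties.method = "first")
    if (any(rowSums(sub) != 1)) {
      abort(paste0("block '", BLOCK_NAMES[bi],
                   "' does not have exactly one 1 in every row"))
    }
    fs$blocks[[bi]][hit]
  })
  names(out) <- BLOCK_NAMES
  as_tibble(out)
}

#' Load a raw binary design from a delimited file
#'
#' For toy inputs and unit fixtures that bypass roster semantics: every
#' column except `yield` must be strictly 0/1, and no block structure is
#' assumed or enforced.
#'
#' @param path CSV/TSV file with binary feature columns and a `yield` column.
#' @return A list with `X` (binary matrix) and `y` (yield vector).
#' @export
load_raw_binary <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tryCatch(
    readr::read_delim(path, delim = delim,
                      col_types = readr::cols(.default = readr::col_double()),
                      progress = FALSE),
    error = function(e) abort(paste0("cannot read '", path, "': ",
                                     conditionMessage(e)))
  )
  if (nrow(tab) == 0 || ncol(tab) < 2 || !"yield" %in% names(tab)) {
    abort("raw binary input needs at least one feature column and a 'yield' column")
  }
  feat <- as.matrix(tab[setdiff(names(tab), "yield")])
  bad <- which(!(feat %in% c(0, 1)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(feat))
    abort(sprintf("non-binary feature value %g at row %d, column '%s'",
                  feat[bad[1]], rc[1], colnames(feat)[rc[2]]))
  }
  list(X = feat, y = tab$yield)
}
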