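#' Build the one-hot feature space observed in a set of records
#'
#' Collects the distinct labels of each of the six categorical blocks
#' (inbred, tester, inbred_cluster, tester_cluster, location, year), sorted
#' lexicographically within a block. Block order is fixed, so column indices
#' of the resulting design matrix — and hence interaction-pattern indexing —
#' are reproducible for a given roster.
#'
#' @param records A trial-record tibble.
#' @return A `feature_space` object: a list with `blocks` (named list of
#'   ordered label vectors) and `p` (total column count).
#' @export
#' @examples
#' sim <- simulate_trials(sim_config(seed = 1))
#' fs <- build_feature_space(sim$records)
#' fs$p
build_feature_space <- function(records) {
  records <- validate_records(records)
  blocks <- lapply(setNames(BLOCK_NAMES, BLOCK_NAMES), function(b) {
    sort(unique(records[[b]]), method = "radix")
  })
  new_feature_space(blocks)
}

new_feature_space <- function(blocks) {
  stopifnot(identical(names(blocks), BLOCK_NAMES))
  for (b in BLOCK_NAMES) {
    if (anyDuplicated(blocks[[b]])) {
      abort(paste0("duplicate labels in block '", b, "'"))
    }
  }
  structure(
    list(blocks = blocks, p = sum(lengths(blocks))),
    class = "feature_space"
  )
}

#' @export
print.feature_space <- function(x, ...) {
  cat("<feature_space> p =", x$p, "columns\n")
  for (b in names(x$blocks)) {
    lab <- x$blocks[[b]]
    cat(sprintf("  %-14s %4d  [%s%s]\n", b, length(lab),
                paste(head(lab, 3), collapse = ", "),
                if (length(lab) > 3) ", ..." else ""))
  }
  invisible(x)
}

#' Column names of a feature space, in design-matrix order
#'
#' @param fs A `feature_space`.
#' @return A character vector of length `fs$p`, formatted `block=label`.
#' @export
feature_names <- function(fs) {
  stopifnot(inherits(fs, "feature_space"))
  unlist(lapply(names(fs$blocks), function(b) {
    paste0(b, "=", fs$blocks[[b]])
  }), use.names = FALSE)
}

# Block id (1..6) for every column of the design matrix.
feature_block_index <- function(fs) {
  rep(seq_along(fs$blocks), lengths(fs$blocks))
}

#' Serialize a feature space to JSON
#'
#' The JSON object maps each block name to its ordered label list, making a
#' fitted model portable across sessions.
#'
#' @param fs A `feature_space`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_feature_space <- function(fs, path) {
  stopifnot(inherits(fs, "feature_space"))
  jsonlite::write_json(fs$blocks, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_feature_space
#' @export
read_feature_space <- function(path) {
  blocks <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- lapply(blocks, as.character)
  new_feature_space(blocks[BLOCK_NAMES])
}
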