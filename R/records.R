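#' Read breeding-trial records from a delimited file
#'
#' Reads one plot observation per row with the columns
#' `inbred, tester, inbred_cluster, tester_cluster, location, year, yield`.
#' The delimiter is chosen from the file extension: `.tsv`/`.txt` are read as
#' tab-separated, anything else as comma-separated.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @return A tibble of trial records with the six label columns as character
#'   and `yield` as double.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' sim <- simulate_trials(sim_config(n_inbreds = 5, n_testers = 4,
#'                                   n_locations = 3, density = 0.5, seed = 1))
#' write_trial_records(sim$records, tf)
#' read_trial_records(tf)
read_trial_records <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("trial-record file not found: ", path))
  }
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  rec <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character(), yield = readr::col_double()
  ), progress = FALSE)
  validate_records(rec)
}

#' Write trial records to a delimited file
#'
#' @param records A trial-record tibble (see [read_trial_records()]).
#' @param path Output path; `.tsv`/`.txt` writes tab-separated, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_trial_records <- function(records, path) {
  records <- validate_records(records)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(records, path, delim = delim)
  invisible(path)
}

#' Validate a trial-record table
#'
#' Checks the schema and the record invariants: all six label fields present
#' and non-empty, and yields finite and positive.
#'
#' @param records A data frame of plot observations.
#' @return The records as a tibble with label columns coerced to character.
#' @export
validate_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("records must be a non-empty data frame")
  }
  missing <- setdiff(RECORD_COLS, names(records))
  if (length(missing) > 0) {
    abort(paste0("records are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  records <- as_tibble(records)[RECORD_COLS]
  records <- dplyr::mutate(records,
                           dplyr::across(dplyr::all_of(BLOCK_NAMES), as.character))
  for (col in BLOCK_NAMES) {
    bad <- is.na(records[[col]]) | records[[col]] == ""
    if (any(bad)) {
      abort(paste0("empty or missing '", col, "' label in row(s) ",
                   paste(head(which(bad), 5), collapse = ", ")))
    }
  }
  y <- records$yield
  if (any(!is.finite(y) | y <= 0)) {
    abort(paste0("yield must be finite and positive; offending row(s) ",
                 paste(head(which(!is.finite(y) | y <= 0), 5), collapse = ", ")))
  }
  records
}

#' Average replicate plots into one record per combination
#'
#' Collapses records sharing the same
#' (inbred, tester, inbred_cluster, tester_cluster, location, year) key into a
#' single record whose yield is the arithmetic mean of the replicate yields.
#' Downstream models are always fitted on this aggregated table, so no
#' combination is ever represented twice.
#'
#' A parent id must carry one genetic-cluster label throughout the data;
#' conflicting labels raise an error naming the parent.
#'
#' @param records A trial-record tibble.
#' @return A tibble with one row per unique key, carrying the mean yield and a
#'   `n_reps` column with the replicate count.
#' @export
aggregate_replicates <- function(records) {
  records <- validate_records(records)
  check_cluster_consistency(records, "inbred", "inbred_cluster")
  check_cluster_consistency(records, "tester", "tester_cluster")
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(BLOCK_NAMES))) |>
    dplyr::summarise(yield = mean(.data$yield), n_reps = dplyr::n(),
                     .groups = "drop")
}

check_cluster_consistency <- function(records, parent_col, cluster_col) {
  tab <- dplyr::distinct(records, .data[[parent_col]], .data[[cluster_col]])
  dup <- tab[[parent_col]][duplicated(tab[[parent_col]])]
  if (length(dup) > 0) {
    abort(paste0("conflicting ", cluster_col, " labels for ", parent_col,
                 "(s): ", paste(unique(dup), collapse = ", ")))
  }
  invisible(records)
}
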