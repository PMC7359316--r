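# Programmatic fixtures shared across test files.

# A minimal valid record tibble; vectors recycle to the longest length.
make_records <- function(inbred = "I1", tester = "T1", ic = "C1", tc = "D1",
                         location = "L1", year = "Y1", yield = 1) {
  tibble::tibble(inbred = inbred, tester = tester, inbred_cluster = ic,
                 tester_cluster = tc, location = location, year = year,
                 yield = yield)
}

# A shuffled table with `n_unique` distinct keys, `n_total` rows in all, and
# deterministic per-key yields; replicate rows share the key but get distinct
# yields so the replicate mean is informative.
make_replicated_records <- function(n_unique = 30, n_total = 50, seed = 42) {
  withr::with_seed(seed, {
    keys <- tibble::tibble(
      inbred = sprintf("I%02d", sample(6, n_unique, replace = TRUE)),
      tester = sprintf("T%02d", sample(5, n_unique, replace = TRUE)),
      location = sprintf("L%02d", sample(4, n_unique, replace = TRUE)),
      year = sprintf("Y%d", sample(2, n_unique, replace = TRUE))
    )
    keys <- dplyr::distinct(keys)
    while (nrow(keys) < n_unique) {
      keys <- dplyr::distinct(dplyr::bind_rows(keys, tibble::tibble(
        inbred = sprintf("I%02d", sample(6, 1)),
        tester = sprintf("T%02d", sample(5, 1)),
        location = sprintf("L%02d", sample(4, 1)),
        year = sprintf("Y%d", sample(2, 1))
      )))
    }
    keys <- keys[seq_len(n_unique), ]
    keys$inbred_cluster <- paste0("C", (as.integer(factor(keys$inbred)) %% 2) + 1)
    keys$tester_cluster <- paste0("D", (as.integer(factor(keys$tester)) %% 2) + 1)
    extra <- keys[sample(n_unique, n_total - n_unique, replace = TRUE), ]
    rec <- dplyr::bind_rows(keys, extra)
    rec$yield <- runif(n_total, 0.8, 1.2)
    rec <- rec[sample(n_total), c("inbred", "tester", "inbred_cluster",
                                  "tester_cluster", "location", "year",
                                  "yield")]
    rec
  })
}

# Small simulated roster for pipeline tests (fast to fit).
small_sim <- function(seed = 5) {
  simulate_trials(sim_config(n_inbreds = 12, n_testers = 10,
                             n_inbred_clusters = 3, n_tester_clusters = 3,
                             n_locations = 6, density = 0.25, seed = seed))
}

small_stacked <- function(sim, seed = 5, ...) {
  fit_stacked(sim$records, rf1 = forest_params(n_trees = 60, n_features = 20),
              rf2 = rf2_params(n_trees = 60), max_K = 2, n_restarts = 2,
              seed = seed, ...)
}
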