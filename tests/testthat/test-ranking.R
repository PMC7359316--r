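test_that("cross grid enumerates every parent pair exactly once", {
  sim <- small_sim(seed = 15)
  mod <- small_stacked(sim, seed = 15)
  g <- cross_grid(mod)
  expect_equal(nrow(g), 12 * 10)
  expect_equal(nrow(unique(g[c("inbred", "tester")])), 12 * 10)
  expect_true(all(is.finite(g$pred)))

  # 2x2 group summary covers all four corners
  sm <- cross_grid_summary(g, q = 0.2)
  expect_equal(nrow(sm), 4)
  high <- sm$mean_pred[sm$inbred_group == "high" & sm$tester_group == "high"]
  low <- sm$mean_pred[sm$inbred_group == "low" & sm$tester_group == "low"]
  expect_gte(high, low)
})

test_that("pair enumeration matches the roster arithmetic", {
  fs <- build_feature_space(make_records(
    inbred = sprintf("I%d", rep_len(1:7, 42)),
    tester = sprintf("T%d", rep_len(1:6, 42))
  ))
  expect_equal(nrow(cross_pairs(fs)), 42)
})

test_that("the grid guard refuses oversized rosters", {
  sim <- small_sim(seed = 16)
  mod <- small_stacked(sim, seed = 16)
  expect_error(cross_grid(mod, max_cells = 10), "max_cells")
})

test_that("top lists use the floor of the quantile fraction", {
  expect_equal(crossgxe:::top_list_size(0.05, 593), 29)
  expect_equal(crossgxe:::top_list_size(0.05, 496), 24)
  expect_equal(crossgxe:::top_list_size(0.05, 10), 1)   # never empty
})

test_that("a dominant planted parent ranks first", {
  cfg <- sim_config(n_inbreds = 10, n_testers = 8, n_inbred_clusters = 2,
                    n_tester_clusters = 2, n_locations = 5, density = 0.5,
                    n_interactions = 0, noise_sd = 0.1, seed = 18)
  sim <- simulate_trials(cfg)
  # promote one inbred far above the rest, regenerating yields from truth
  enc <- encode_records(aggregate_replicates(sim$records), sim$fs)
  boost <- 5 * sd(sim$records$yield)
  col <- which(feature_names(sim$fs) == "inbred=I003")
  rec <- aggregate_replicates(sim$records)
  rec$yield <- rec$yield + boost * enc$X[, col]
  rec$n_reps <- NULL
  mod <- fit_stacked(rec, rf1 = forest_params(n_trees = 60, n_features = 20),
                     rf2 = rf2_params(n_trees = 60), max_K = 1,
                     n_restarts = 2, seed = 18)
  rk <- rank_parents(mod, rec, q = 0.2)
  expect_equal(rk$inbreds$inbred[1], "I003")
  expect_true(all(rk$consistency$consistent <= rk$consistency$list_size))
  # top and bottom predicted lists are disjoint
  sz <- rk$consistency$list_size[1]
  top <- rk$inbreds$inbred[seq_len(sz)]
  bot <- rev(rk$inbreds$inbred)[seq_len(sz)]
  expect_length(intersect(top, bot), 0)
})

test_that("cluster summaries cover every cluster and a planted shift wins", {
  sim <- small_sim(seed = 20)
  mod <- small_stacked(sim, seed = 20)
  cs <- cluster_summary(mod)
  expect_equal(sum(cs$pool == "inbred"), 3)
  expect_equal(sum(cs$pool == "tester"), 3)
  # single-cluster roster: the cluster mean is the global mean
  rec <- sim$records
  rec$inbred_cluster <- "C1"; rec$tester_cluster <- "D1"
  mod1 <- fit_stacked(rec, rf1 = forest_params(n_trees = 30, n_features = 10),
                      rf2 = rf2_params(n_trees = 30), max_K = 1,
                      n_restarts = 1, seed = 20)
  cs1 <- cluster_summary(mod1)
  agg <- aggregate_replicates(rec)
  expect_equal(cs1$observed[cs1$pool == "inbred"], mean(agg$yield))
})

test_that("plot builders return ggplot objects", {
  sim <- small_sim(seed = 25)
  mod <- small_stacked(sim, seed = 25)
  g <- cross_grid(mod)
  expect_s3_class(plot_cross_grid(g, q = 0.2), "gg")
  expect_s3_class(plot_pred_obs(sim$records$yield,
                                predict(mod, sim$records)), "gg")
  expect_s3_class(autoplot(mod$gxe), "gg")
  cv <- cross_validate(sim$records, model = "rf1", k = 3, seed = 25,
                       rf1 = forest_params(n_trees = 20, n_features = 10))
  expect_s3_class(autoplot(cv), "gg")
})
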