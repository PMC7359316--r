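test_that("a forest on a constant response predicts the constant", {
  X <- matrix(rbinom(100, 1, 0.5), 25, 4)
  fit <- fit_rf(X, rep(2.5, 25), forest_params(n_trees = 30, n_features = 2),
                seed = 1)
  expect_equal(predict(fit, X), rep(2.5, 25), tolerance = 1e-12)
})

test_that("a forest learns an obvious signal", {
  withr::with_seed(2, {
    X <- matrix(rnorm(1000 * 5), 1000, 5)
    y <- X[, 1] * 2 + X[, 2] + rnorm(1000, 0, sqrt(5 / 5)) * 0
    y <- y + rnorm(1000, 0, sd(y) / sqrt(5))   # snr ~ 5
  })
  fit <- fit_rf(X, y, forest_params(n_trees = 100, n_features = 3), seed = 2)
  r2 <- yield_metrics(y, predict(fit, X))$r2
  expect_gt(r2, 0.5)
})

test_that("oversized feature counts are clamped with a warning", {
  X <- matrix(rbinom(60, 1, 0.5), 20, 3)
  expect_warning(fit <- fit_rf(X, rnorm(20),
                               forest_params(n_trees = 20, n_features = 50),
                               seed = 3),
                 "clamp")
  expect_equal(fit$q, 3)
})

test_that("forest fits are deterministic given the seed", {
  X <- matrix(rbinom(200, 1, 0.5), 50, 4)
  y <- rnorm(50)
  f1 <- fit_rf(X, y, forest_params(n_trees = 50, n_features = 2), seed = 7)
  f2 <- fit_rf(X, y, forest_params(n_trees = 50, n_features = 2), seed = 7)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_identical(f1$oob, f2$oob)
})

test_that("the stacked pipeline runs end to end and is deterministic", {
  sim <- small_sim(seed = 5)
  m1 <- small_stacked(sim, seed = 5)
  m2 <- small_stacked(sim, seed = 5)
  p1 <- predict(m1, sim$records)
  expect_identical(p1, predict(m2, sim$records))
  expect_true(all(is.finite(p1)))
  expect_length(p1, nrow(sim$records))

  # permutation equivariance of prediction
  perm <- withr::with_seed(1, sample(nrow(sim$records)))
  expect_equal(predict(m1, sim$records[perm, ]), p1[perm])
})

test_that("prediction refuses labels outside the training roster", {
  sim <- small_sim(seed = 6)
  mod <- small_stacked(sim, seed = 6)
  new <- sim$records[1, ]
  new$inbred <- "UNSEEN"
  expect_error(predict(mod, new), "UNSEEN")
})

test_that("with no detected interactions the stack reduces to RF1 plus a constant", {
  # additive-only truth at low noise: the search finds nothing to add
  cfg <- sim_config(n_inbreds = 10, n_testers = 8, n_inbred_clusters = 2,
                    n_tester_clusters = 2, n_locations = 5, density = 0.3,
                    n_interactions = 0, seed = 8)
  sim <- simulate_trials(cfg)
  mod <- fit_stacked(sim$records, rf1 = forest_params(n_trees = 40,
                                                      n_features = 15),
                     rf2 = rf2_params(n_trees = 40), max_K = 1,
                     n_restarts = 2, tol = 0.02, seed = 8)
  if (mod$gxe$K == 0) {
    enc <- encode_records(aggregate_replicates(sim$records), mod$fs)
    diff <- predict(mod, sim$records) -
      predict(mod$rf1, encode_records(sim$records, mod$fs)$X)
    expect_lt(max(diff) - min(diff), 1e-12)
  } else {
    expect_equal(mod$rf2$q, mod$gxe$K)
  }
})

test_that("the tiny worked example survives the full pipeline as a smoke test", {
  fx <- figure2_fixture()
  # express the 8 plants as roster records: parents carry gene/soil, year
  # carries weather
  rec <- tibble::tibble(
    inbred = paste0("G", fx$X[, "gene"]),
    tester = paste0("S", fx$X[, "soil"]),
    inbred_cluster = paste0("GC", fx$X[, "gene"]),
    tester_cluster = paste0("SC", fx$X[, "soil"]),
    location = "L1",
    year = paste0("W", fx$X[, "weather"]),
    yield = fx$y
  )
  expect_no_error(
    mod <- fit_stacked(rec, rf1 = forest_params(n_trees = 10, n_features = 2),
                       rf2 = rf2_params(n_trees = 10), max_K = 1,
                       inner_k = 1, n_restarts = 1, seed = 1)
  )
  expect_length(predict(mod, rec), 8)
})

test_that("stacked model bundles survive the save/load round trip", {
  sim <- small_sim(seed = 9)
  mod <- small_stacked(sim, seed = 9)
  dir <- withr::local_tempdir()
  write_stacked_model(mod, dir)
  expect_true(all(file.exists(file.path(dir, c("feature_space.json",
                                               "gxe_model.json",
                                               "manifest.json")))))
  back <- read_stacked_model(dir)
  expect_equal(predict(back, sim$records), predict(mod, sim$records))
})
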