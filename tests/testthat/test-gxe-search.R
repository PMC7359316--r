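test_that("the search explains the worked example exactly", {
  fx <- figure2_fixture()
  fit <- search_interactions(fx$X, fx$y, max_K = 3, max_order = 2,
                             n_restarts = 3, inner_k = 1, seed = 1)
  expect_equal(fit$K, 3)
  expect_lt(fit$training_sse, 1e-12)
})

test_that("purely additive noiseless data yields no interactions", {
  sim <- simulate_binary_design(200, 6, NULL, b = numeric(0),
                                noise_sd = 0, seed = 3)
  fit <- search_interactions(sim$X, sim$y, max_K = 3, inner_k = 5, seed = 3)
  expect_equal(fit$K, 0)
})

test_that("a zero-variance response returns an additive model with warning", {
  X <- matrix(rbinom(40, 1, 0.5), 10, 4)
  expect_warning(fit <- search_interactions(X, rep(1, 10), seed = 1),
                 "zero variance")
  expect_equal(fit$K, 0)
})

test_that("a planted two-way interaction is recovered across seeds", {
  hits <- 0
  for (sd in 1:10) {
    alpha <- rbind(c(1, 1, rep(0.5, 6)))
    sim <- simulate_binary_design(500, 8, alpha, b = 0.5, noise_sd = 0.02,
                                  seed = sd)
    fit <- search_interactions(sim$X, sim$y, max_K = 2, max_order = 2,
                               n_restarts = 3, inner_k = 5, seed = sd)
    sigs <- if (fit$K > 0) {
      apply(fit$alpha, 1, function(a) paste(which(a != 0.5), collapse = "+"))
    } else character(0)
    hits <- hits + ("1+2" %in% sigs)
  }
  expect_gte(hits, 8)
})

test_that("the heuristic never beats and often matches the brute-force oracle", {
  equal_noiseless <- 0
  for (i in 1:6) {
    withr::with_seed(400 + i, {
      p <- sample(3:4, 1)
      a <- rep(0.5, p); a[sample(p, 2)] <- sample(0:1, 2, replace = TRUE)
    })
    sim <- simulate_binary_design(12, p, rbind(a), b = 2, noise_sd = 0,
                                  seed = 500 + i)
    h <- search_interactions(sim$X, sim$y, max_K = 1, max_order = 2,
                             n_restarts = 6, inner_k = 1, seed = i)
    o <- brute_force_search(sim$X, sim$y, K = 1, max_order = 2)
    expect_gte(h$training_sse, o$training_sse - 1e-8)
    equal_noiseless <- equal_noiseless +
      (abs(h$training_sse - o$training_sse) < 1e-8)
  }
  expect_equal(equal_noiseless, 6)
})

test_that("brute force respects its budget and K limits", {
  X <- matrix(rbinom(40, 1, 0.5), 10, 4)
  y <- rnorm(10)
  expect_error(brute_force_search(matrix(0, 4, 13), y[1:4]), "p <= 12")
  expect_error(brute_force_search(X, y, K = 3), "K in")
  expect_error(brute_force_search(X, y, K = 1, max_order = 4, budget = 10),
               "budget")
  # K = 0 reduces to the additive fit
  expect_equal(brute_force_search(X, y, K = 0)$training_sse,
               fit_gxe(X, y)$training_sse)
})

test_that("a single best pattern strictly improves the worked example", {
  fx <- figure2_fixture()
  add <- fit_gxe(fx$X, fx$y)
  one <- brute_force_search(fx$X, fx$y, K = 1, max_order = 2)
  expect_lt(one$training_sse, add$training_sse)
})

test_that("brute force with two slots finds the planted noiseless pair", {
  alpha <- rbind(c(1, 1, 0.5, 0.5), c(0.5, 0.5, 0, 1))
  sim <- simulate_binary_design(40, 4, alpha, b = c(1.5, -2), noise_sd = 0,
                                seed = 77)
  o <- brute_force_search(sim$X, sim$y, K = 2, max_order = 2)
  expect_lt(o$training_sse, 1e-16)
})

test_that("the search is deterministic under a fixed seed", {
  sim <- simulate_binary_design(300, 10, rbind(c(1, 1, rep(0.5, 8))),
                                b = 0.4, noise_sd = 0.05, seed = 9)
  f1 <- search_interactions(sim$X, sim$y, max_K = 2, seed = 99)
  f2 <- search_interactions(sim$X, sim$y, max_K = 2, seed = 99)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$b, f2$b)
})

test_that("interaction summaries report the worked example faithfully", {
  fx <- figure2_fixture()
  fit <- fit_gxe(fx$X, fx$y, fx$truth$alpha)
  tab <- summarize_interactions(fit)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$order, rep(2L, 3))
  expect_setequal(round(tab$effect, 10), c(-1, 1, 2))
  expect_equal(tab$n_members, rep(2L, 3))

  empty <- summarize_interactions(fit_gxe(fx$X, fx$y))
  expect_equal(nrow(empty), 0)
})
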