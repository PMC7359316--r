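test_that("membership implements the X + alpha != 1 rule", {
  fx <- figure2_fixture()
  # the infertile-soil, dry-weather pattern selects exactly the two
  # (soil = 0, weather = 0) rows
  m1 <- membership(c(0.5, 0, 0), fx$X)
  expect_equal(sum(m1), 2)
  expect_equal(which(m1 == 1), which(fx$X[, "soil"] == 0 & fx$X[, "weather"] == 0))

  # all-neutral pattern matches everyone
  expect_equal(membership(rep(0.5, 3), fx$X), rep(1, 8))

  # random designs agree with a naive double-loop oracle
  withr::with_seed(11, {
    for (rep in 1:5) {
      X <- matrix(rbinom(60, 1, 0.5), 12, 5)
      a <- sample(c(0, 0.5, 1), 5, replace = TRUE)
      oracle <- vapply(seq_len(12), function(i) {
        as.numeric(all(vapply(1:5, function(j) {
          X[i, j] + a[j] != 1
        }, logical(1))))
      }, numeric(1))
      expect_equal(membership(a, X), oracle)
    }
  })
})

test_that("membership validates pattern length and values", {
  X <- matrix(0:1, 2, 2)
  expect_error(membership(c(0, 0.5, 1), X), "length")
  expect_error(membership(c(0.3, 1), X), "0, 0.5, or 1")
})

test_that("build_Z stacks membership columns, handles K = 0 and duplicates", {
  fx <- figure2_fixture()
  Z <- build_Z(fx$truth$alpha, fx$X)
  expect_equal(dim(Z), c(8, 3))
  expect_equal(unname(colSums(Z)), c(2, 2, 2))

  expect_equal(dim(build_Z(NULL, fx$X)), c(8, 0))

  dup <- rbind(fx$truth$alpha[1, ], fx$truth$alpha[1, ])
  Zd <- build_Z(dup, fx$X)
  expect_equal(Zd[, 1], Zd[, 2])
})

test_that("membership is anti-monotone in added constraints", {
  withr::with_seed(21, {
    X <- matrix(rbinom(200, 1, 0.5), 40, 5)
    for (rep in 1:10) {
      a <- rep(0.5, 5)
      act <- sample(5, 2)
      a[act] <- sample(0:1, 2, replace = TRUE)
      base <- membership(a, X)
      j <- sample(setdiff(1:5, act), 1)
      for (v in c(0, 1)) {
        a2 <- a; a2[j] <- v
        expect_true(all(membership(a2, X) <= base))
      }
    }
  })
})

test_that("an order-o pattern on a full factorial matches n / 2^o rows", {
  p <- 4
  X <- as.matrix(expand.grid(rep(list(0:1), p)))
  withr::with_seed(31, {
    for (o in 2:4) {
      a <- rep(0.5, p)
      js <- sample(p, o)
      a[js] <- sample(0:1, o, replace = TRUE)
      expect_equal(sum(membership(a, X)), nrow(X) / 2^o)
    }
  })
})

test_that("the worked-example coefficients are recovered exactly", {
  fx <- figure2_fixture()
  fit <- fit_gxe(fx$X, fx$y, fx$truth$alpha)
  expect_equal(fit$beta0, 2)
  expect_equal(unname(fit$beta), c(1, 0, 2), tolerance = 1e-10)
  expect_equal(fit$b, c(-1, 1, 2), tolerance = 1e-10)
  expect_lt(fit$training_sse, 1e-20)
  # prediction reproduces the training yields and extrapolates the stated
  # effect sum for the all-ones plant
  expect_equal(predict(fit, fx$X), fx$y, tolerance = 1e-10)
  expect_equal(predict(fit, matrix(c(1, 1, 1), 1)), 8, tolerance = 1e-10)
})

test_that("an interaction-free fit on constant data is exact", {
  X <- matrix(0, 5, 1)
  fit <- fit_gxe(X, rep(3, 5))
  expect_equal(unname(fit$beta0 + 0 * fit$beta[1]), 3)
  expect_lt(fit$training_sse, 1e-20)
  expect_equal(predict(fit, X), rep(3, 5))
})

test_that("least-squares effects match an independent pseudoinverse oracle", {
  skip_if_not_installed("pracma")
  withr::with_seed(41, {
    for (rep in 1:3) {
      X <- matrix(rbinom(80, 1, 0.5), 20, 4)
      a <- rbind(c(1, 1, 0.5, 0.5), c(0.5, 0, 0.5, 1))
      y <- rnorm(20)
      fit <- fit_gxe(X, y, a)
      A <- cbind(1, X, build_Z(a, X))
      ref <- drop(pracma::pinv(A) %*% y)
      expect_equal(c(fit$beta0, unname(fit$beta), fit$b), ref,
                   tolerance = 1e-8)
    }
  })
})

test_that("training SSE never increases when a membership column is added", {
  withr::with_seed(51, {
    X <- matrix(rbinom(120, 1, 0.5), 30, 4)
    y <- rnorm(30)
    pats <- rbind(c(1, 0, 0.5, 0.5), c(0.5, 1, 1, 0.5), c(0, 0.5, 0.5, 1))
    sse <- vapply(0:3, function(k) {
      fit_gxe(X, y, if (k == 0) NULL else pats[seq_len(k), , drop = FALSE])$training_sse
    }, numeric(1))
    expect_true(all(diff(sse) <= 1e-10))
  })
})

test_that("tidy and glance expose the model in broom shape", {
  fx <- figure2_fixture()
  fit <- fit_gxe(fx$X, fx$y, fx$truth$alpha)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1 + 3 + 3)   # intercept + additive + interactions
  expect_equal(td$estimate[td$type == "interaction"], c(-1, 1, 2),
               tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$K, 3L)
  expect_equal(gl$max_order, 2L)
})

test_that("a fitted model survives the JSON round trip", {
  fx <- figure2_fixture()
  fit <- fit_gxe(fx$X, fx$y, fx$truth$alpha)
  path <- withr::local_tempfile(fileext = ".json")
  write_gxe_model(fit, path)
  back <- read_gxe_model(path)
  expect_equal(back$beta0, fit$beta0)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$alpha, fit$alpha, ignore_attr = TRUE)
  expect_equal(back$b, fit$b)
  expect_equal(predict(back, fx$X), predict(fit, fx$X))
})
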