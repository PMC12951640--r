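test_that("constant channels normalize to beta through the variance floor", {
  st <- norm_state("IN", 3)
  st$beta <- c(-1, 0, 2.5)
  x <- array(5, dim = c(4, 4, 3, 2))
  y <- normalize_train(x, st)$y
  for (j in 1:3) expect_equal(max(abs(y[, , j, ] - st$beta[j])), 0, tolerance = 1e-6)
})

test_that("instance normalization matches its closed form per instance and channel", {
  set.seed(2)
  st <- norm_state("IN", 4)
  st$gamma <- runif(4, 0.5, 2)
  st$beta <- rnorm(4)
  x <- array(rnorm(2 * 4 * 8 * 8, mean = 3, sd = 2), dim = c(8, 8, 4, 2))
  y <- normalize_train(x, st)$y
  mus <- apply(y, c(3, 4), mean)
  sds <- apply(y, c(3, 4), function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(sweep(mus, 1, st$beta))), 1e-10)
  expect_lt(max(abs(sweep(sds, 1, abs(st$gamma), "/") - 1)), 1e-3)
})

test_that("BN updates moving averages; momentum-free single batch stores the batch mean", {
  set.seed(3)
  st <- norm_state("BN", 2, momentum = 1)
  x <- array(rnorm(6 * 6 * 2 * 3, mean = 7), dim = c(6, 6, 2, 3))
  st2 <- normalize_train(x, st)$state
  for (j in 1:2) {
    expect_equal(st2$moving_mean[j], mean(x[, , j, ]))
    expect_equal(st2$moving_var[j], mean((x[, , j, ] - mean(x[, , j, ]))^2))
  }
})

test_that("TTIN is invariant to per-channel affine input perturbation", {
  set.seed(4)
  st <- norm_state("IN", 4)
  st$gamma <- runif(4, 0.5, 2); st$beta <- rnorm(4)
  x1 <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4, 1))
  x2 <- x1
  for (j in 1:4) x2[, , j, 1] <- 3.2 * x2[, , j, 1] + j
  expect_lt(max(abs(normalize_ttin(x1, st) - normalize_ttin(x2, st))), 1e-4)
})

test_that("TTIN statistics: channel mean equals beta, std approaches |gamma|", {
  set.seed(5)
  st <- norm_state("IN", 6)
  st$gamma <- runif(6, -2, 2); st$beta <- rnorm(6)
  x <- array(rnorm(16 * 16 * 6, sd = 4), dim = c(16, 16, 6, 1))
  y <- normalize_ttin(x, st)
  for (j in 1:6) {
    expect_lt(abs(mean(y[, , j, 1]) - st$beta[j]), 1e-4)
    expect_lt(abs(sqrt(mean((y[, , j, 1] - mean(y[, , j, 1]))^2)) -
                    abs(st$gamma[j])), 1e-3)
  }
})

test_that("TTIN equals IN-mode training at batch size one, and rejects larger batches", {
  set.seed(6)
  st <- norm_state("IN", 3)
  st$gamma <- runif(3); st$beta <- rnorm(3)
  x <- array(rnorm(5 * 7 * 3), dim = c(5, 7, 3, 1))
  expect_equal(normalize_ttin(x, st), normalize_train(x, st)$y)
  xb <- array(rnorm(5 * 7 * 3 * 2), dim = c(5, 7, 3, 2))
  expect_error(normalize_ttin(xb, st), "batch size one")
})

test_that("BN inference with moving statistics is a pure affine map", {
  set.seed(7)
  st <- norm_state("BN", 3)
  st$gamma <- runif(3); st$beta <- rnorm(3)
  st$moving_mean <- rnorm(3); st$moving_var <- runif(3, 0.5, 2)
  fwd <- function(x) mstta:::.norm_forward(x, st, 15L, phase = "bn_infer")$y
  x1 <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3, 1))
  x2 <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3, 1))
  z <- array(0, dim = dim(x1))
  # affine: f(x1 + x2) = f(x1) + f(x2) - f(0)
  expect_equal(fwd(x1 + x2), fwd(x1) + fwd(x2) - fwd(z), tolerance = 1e-10)
})

test_that("CondIN keeps 15 parameter sets selected bijectively by combination", {
  st <- norm_state("CondIN", 3)
  expect_equal(nrow(st$gamma), 15L)
  set.seed(8)
  st$gamma <- matrix(rnorm(45), 15, 3)
  st$beta <- matrix(rnorm(45), 15, 3)
  seen <- t(vapply(1:15, function(k) select_affine(st, k)$gamma, numeric(3)))
  expect_equal(seen, st$gamma, ignore_attr = TRUE)
  expect_equal(nrow(unique(seen)), 15L)
  # bitmask order: FLAIR alone is bit 4 -> index 8
  expect_equal(combo_index(c(FALSE, FALSE, FALSE, TRUE)), 8L)
  expect_equal(combo_index(c(TRUE, TRUE, TRUE, TRUE)), 15L)
  expect_error(combo_index(rep(FALSE, 4)), "non-empty")
  expect_error(select_affine(st, 0L), "1..15")
  # BN/IN: one shared set for any combination
  stb <- norm_state("BN", 3)
  expect_identical(select_affine(stb, 1L), select_affine(stb, 15L))
})

test_that("training a single combination touches only that combination's parameters", {
  set.seed(9)
  st <- norm_state("CondIN", 2)
  x <- array(rnorm(4 * 4 * 2 * 3), dim = c(4, 4, 2, 3))
  combo <- 5L
  r <- mstta:::.norm_forward(x, st, combo, phase = "train")
  gy <- array(rnorm(length(x)), dim = dim(x))
  gb <- mstta:::.norm_backward(gy, st, r$cache)
  expect_true(all(gb$ggamma[-combo, ] == 0))
  expect_true(all(gb$gbeta[-combo, ] == 0))
  expect_true(any(gb$ggamma[combo, ] != 0))
  # mixed-combination batches accumulate into their own rows only
  r2 <- mstta:::.norm_forward(x, st, c(2L, 9L, 2L), phase = "train")
  gb2 <- mstta:::.norm_backward(gy, st, r2$cache)
  expect_true(all(gb2$gbeta[-c(2L, 9L), ] == 0))
})
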