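test_that("kNN predictions match hand-worked cases", {
  fit <- knn_fit(matrix(c(0, 1, 2), 3, 1), c(0, 10, 20), k = 2,
                 normalize = FALSE)
  expect_equal(predict(fit, 0.6), 5)          # neighbours at 1 and 0

  # k = m: the global training mean
  fitm <- knn_fit(matrix(rnorm(5), 5, 1), c(1, 2, 3, 4, 10), k = 5)
  expect_equal(predict(fitm, 0), 4)

  # query equal to a training point with k = 1 returns its target
  x <- matrix(c(1, 5, 9), 3, 1)
  fit1 <- knn_fit(x, c(11, 55, 99), k = 1)
  expect_equal(predict(fit1, 5), 55)

  expect_error(knn_fit(matrix(1:4, 4, 1), 1:4, k = 5), "exceeds")
})

test_that("kNN agrees with an exhaustive-search oracle and stays in target range", {
  oracle <- function(train_x, train_y, k, query) {
    d <- numeric(nrow(train_x))
    for (i in seq_len(nrow(train_x))) {
      d[i] <- sqrt(sum((train_x[i, ] - query)^2))
    }
    taken <- integer(0)
    for (j in seq_len(k)) {                 # selection sort with index ties
      best <- which(!seq_along(d) %in% taken &
                      d == min(d[setdiff(seq_along(d), taken)]))[1]
      taken <- c(taken, best)
    }
    mean(train_y[taken])
  }
  set.seed(2024)
  for (rep in 1:50) {
    m <- sample(5:40, 1)
    d <- sample(1:6, 1)
    train_x <- matrix(rnorm(m * d), m, d)
    train_y <- rnorm(m, 100, 50)
    k <- sample(seq_len(min(m, 15)), 1)
    fit <- knn_fit(train_x, train_y, k = k, normalize = FALSE)
    query <- rnorm(d)
    got <- predict(fit, query)
    expect_identical(got, oracle(train_x, train_y, k, query))
    expect_gte(got, min(train_y))
    expect_lte(got, max(train_y))
  }
})

test_that("kNN predictions are invariant to training-sample permutation", {
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  q <- matrix(rnorm(15), 5, 3)
  base <- predict(knn_fit(x, y, k = 4), q)
  for (i in 1:5) {
    p <- sample(20)
    expect_equal(predict(knn_fit(x[p, ], y[p], k = 4), q), base)
  }
})

test_that("the network forward pass composes affine maps and activations", {
  # single linear layer: omega = 2, b = 1, input 3 -> 7
  w <- list(list(W = matrix(2, 1, 1), b = 1))
  expect_equal(drop(mlp_forward(w, 3)), 7)

  # all-zero weights and biases produce the zero function
  zero <- list(list(W = matrix(0, 2, 4), b = rep(0, 4)),
               list(W = matrix(0, 4, 1), b = 0))
  expect_equal(drop(mlp_forward(zero, c(5, -3))), 0)

  # independent loop-coded oracle on random weights
  set.seed(44)
  w2 <- mlp_init(c(3, 5, 1), seed = 44)
  x <- rnorm(3)
  a <- x
  for (l in 1:2) {
    z <- drop(a %*% w2[[l]]$W) + w2[[l]]$b
    a <- if (l < 2) 1 / (1 + exp(-z)) else z
  }
  expect_equal(drop(mlp_forward(w2, x)), a, tolerance = 1e-14)
})

test_that("backprop gradients match central finite differences", {
  set.seed(17)
  rel_err <- function(a, b) abs(a - b) / pmax(abs(a) + abs(b), 1e-10)
  for (rep in 1:5) {
    sizes <- c(sample(2:4, 1), sample(2:5, 1), 1)
    w <- mlp_init(sizes, seed = rep)
    x <- matrix(rnorm(6 * sizes[1]), 6, sizes[1])
    y <- rnorm(6)
    g <- mlp_gradient(w, x, y)
    h <- 1e-6
    for (l in seq_along(w)) {
      for (i in seq_along(w[[l]]$W)) {
        wp <- w; wp[[l]]$W[i] <- wp[[l]]$W[i] + h
        wm <- w; wm[[l]]$W[i] <- wm[[l]]$W[i] - h
        fd <- (mlp_loss(wp, x, y) - mlp_loss(wm, x, y)) / (2 * h)
        expect_lt(rel_err(g[[l]]$W[i], fd), 1e-5)
      }
      for (i in seq_along(w[[l]]$b)) {
        bp <- w; bp[[l]]$b[i] <- bp[[l]]$b[i] + h
        bm <- w; bm[[l]]$b[i] <- bm[[l]]$b[i] - h
        fd <- (mlp_loss(bp, x, y) - mlp_loss(bm, x, y)) / (2 * h)
        expect_lt(rel_err(g[[l]]$b[i], fd), 1e-5)
      }
    }
  }
})

test_that("training is deterministic, improves on the mean, and fails loudly", {
  set.seed(8)
  x <- matrix(runif(30), 30, 1)
  y <- 2 * drop(x) + 1
  m1 <- mlp_train(x, y, epochs = 2000, seed = 5)
  m2 <- mlp_train(x, y, epochs = 2000, seed = 5)
  expect_identical(m1$weights, m2$weights)     # bit-identical under one seed

  pred <- predict(m1, x)
  rmse <- sqrt(mean((pred - y)^2))
  baseline <- sqrt(mean((mean(y) - y)^2))
  expect_lt(rmse, baseline)

  # zero epochs: the model is exactly its initialisation
  m0 <- mlp_train(x, y, epochs = 0, seed = 5)
  expect_identical(m0$weights, mlp_init(m0$layer_sizes, seed = 5))

  expect_error(mlp_train(x, y, learning_rate = 1e6, epochs = 50, seed = 1),
               "epoch")
})

test_that("models round-trip through JSON with identical predictions", {
  set.seed(12)
  x <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20, 50, 10)
  q <- matrix(rnorm(10), 5, 2)

  kfit <- knn_fit(x, y, k = 3)
  pk <- withr::local_tempfile(fileext = ".json")
  write_model(kfit, pk)
  expect_equal(predict(read_model(pk), q), predict(kfit, q))

  mfit <- mlp_train(x, y, epochs = 50, seed = 2)
  pm <- withr::local_tempfile(fileext = ".json")
  write_model(mfit, pm)
  expect_equal(predict(read_model(pm), q), predict(mfit, q))
})
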