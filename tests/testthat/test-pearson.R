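test_that("pearson_r hits the exact linear limits and matches a two-pass oracle", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)

  # independent two-pass population-covariance oracle on 1000 random pairs
  set.seed(123)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(3:50, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.5 * x
    num <- sum((x - sum(x) / n) * (y - sum(y) / n)) / n
    den <- sqrt(sum((x - sum(x) / n)^2) / n) * sqrt(sum((y - sum(y) / n)^2) / n)
    worst <- max(worst, abs(pearson_r(x, y) - num / den))
  }
  expect_lt(worst, 1e-12)

  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_r(1, 2), "length")
})

test_that("pearson_r is symmetric, affine-invariant and sign-flips under negation", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15)
    r <- pearson_r(x, y)
    expect_lte(abs(r), 1)
    expect_equal(pearson_r(y, x), r)
    expect_equal(pearson_r(2.5 * x + 3, y), r, tolerance = 1e-12)
    expect_equal(pearson_r(x, 0.1 * y - 7), r, tolerance = 1e-12)
    expect_equal(pearson_r(-x, y), -r, tolerance = 1e-12)
  }
})

test_that("pearson_stats exposes the population moments", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 2, 4, 4)
  st <- pearson_stats(x, y)
  expect_equal(st$mean_x, 2.5)
  expect_equal(st$cov, mean((x - 2.5) * (y - 3)))          # 1/n covariance
  expect_equal(st$sd_x, sqrt(mean((x - 2.5)^2)))            # 1/n sd
  expect_equal(st$rho, st$cov / (st$sd_x * st$sd_y))
})

test_that("attribute ranking puts a duplicated target first and zeroes constants", {
  set.seed(21)
  n <- 200
  y <- rnorm(n)
  values <- cbind(dup = y, noise = rnorm(n), const = rep(3, n))
  tab <- sample_table(values, y)
  expect_warning(rk <- rank_attributes(tab), "constant")
  expect_equal(rk$order[1], 1L)
  expect_equal(abs(rk$coefficients[["dup"]]), 1)
  expect_equal(rk$coefficients[["const"]], 0)
  expect_lt(abs(rk$coefficients[["noise"]]), 3 / sqrt(n))

  expect_error(rank_attributes(sample_table(cbind(a = rnorm(5)), rep(1, 5))),
               "zero variance")
})

test_that("the ranked-removal sweep discards the noise attribute", {
  set.seed(5)
  n <- 60
  signal <- runif(n)
  values <- cbind(signal = signal,
                  dup = signal,            # exact duplicate
                  noise = rnorm(n))
  tab <- sample_table(values, target = signal * 100)
  sw <- sweep_select(tab, n_folds = 5, seed = 1)
  expect_s3_class(sw, "pearson_sweep")
  expect_false(3L %in% sw$best_subset)

  # exhaustive evaluation over all 7 non-empty subsets confirms: the best
  # subset found scores no worse than any subset containing the noise column
  folds <- make_folds(n, 5, seed = 1)
  cv_rmse <- function(attrs) {
    best <- Inf
    for (k in c(1, 3, 5, 7, 9, 11, 13, 15)) {
      pred <- numeric(n)
      for (f in 1:5) {
        te <- folds$fold_assignments == f
        fit <- knn_fit(tab$values[!te, attrs, drop = FALSE],
                       tab$target[!te], k = k)
        pred[te] <- predict(fit, tab$values[te, attrs, drop = FALSE])
      }
      best <- min(best, sqrt(mean((pred - tab$target)^2)))
    }
    best
  }
  subsets <- unlist(lapply(1:3, function(k) combn(3, k, simplify = FALSE)),
                    recursive = FALSE)
  scores <- vapply(subsets, cv_rmse, numeric(1))
  with_noise <- vapply(subsets, function(s) 3L %in% s, logical(1))
  expect_lte(min(sw$per_size_scores), min(scores[with_noise]))

  # the sweep's nested subsets only ever contain top-ranked attributes
  expect_true(all(vapply(seq_along(sw$subsets), function(i) {
    setequal(sw$subsets[[i]],
             sort(sw$ranking$order[seq_len(length(sw$subsets[[i]]))]))
  }, logical(1))))
})

test_that("sweep degenerates gracefully and its full-size entry is plain kNN", {
  set.seed(9)
  tab <- random_table(n = 25, d = 1, seed = 9)
  sw1 <- sweep_select(tab, n_folds = 5, seed = 2)
  expect_length(sw1$per_size_scores, 1)
  expect_equal(sw1$best_size, 1L)

  tab3 <- random_table(n = 25, d = 3, seed = 10)
  sw3 <- sweep_select(tab3, n_folds = 5, seed = 2)
  expect_length(sw3$per_size_scores, 3)
  # size-3 row of the sweep equals a direct all-attribute kNN evaluation
  folds <- make_folds(25, 5, seed = 2)
  for (k in c(1, 3)) {
    pred <- numeric(25)
    for (f in 1:5) {
      te <- folds$fold_assignments == f
      fit <- knn_fit(tab3$values[!te, , drop = FALSE], tab3$target[!te], k = k)
      pred[te] <- predict(fit, tab3$values[te, , drop = FALSE])
    }
    expect_equal(sw3$grid["3", paste0("k=", k)],
                 sqrt(mean((pred - tab3$target)^2)))
  }
  # best score cannot exceed the all-features score
  expect_lte(min(sw3$per_size_scores), sw3$per_size_scores[["3"]])

  # literal drop order removes the strongest-ranked attribute first
  swl <- sweep_select(tab3, n_folds = 5, seed = 2, drop_order = "literal")
  expect_equal(swl$subsets[["2"]], sort(swl$ranking$order[2:3]))
})
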