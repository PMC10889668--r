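test_that("approximations obey the crisp, rough and brute-force set laws", {
  fx <- separated_clusters()
  part <- generate_gb_partition(fx$values, fx$labels, 1:2)
  ap <- gb_approximate(part, fx$labels, 1L)
  expect_equal(ap$lower, 1:5)      # all balls pure: lower = upper = concept
  expect_equal(ap$upper, 1:5)

  # fully rough: one mixed unsplittable ball holding the concept's samples
  same <- matrix(0, 4, 1)
  mixed <- generate_gb_partition(same, c(1L, 2L, 2L, 2L), 1)
  ap2 <- gb_approximate(mixed, c(1L, 2L, 2L, 2L), 1L)
  expect_length(ap2$lower, 0)
  expect_equal(ap2$upper, 1:4)

  expect_error(gb_approximate(part, fx$labels, 99L), "unknown class")

  # 12-sample fixture against exhaustive set arithmetic
  set.seed(31)
  values <- matrix(sample(c(0, 0.5, 1), 24, replace = TRUE), 12, 2)
  labels <- sample(1:3, 12, replace = TRUE)
  part3 <- generate_gb_partition(values, labels, 1:2)
  for (concept in sort(unique(labels))) {
    ap3 <- gb_approximate(part3, labels, concept)
    lower <- integer(0)
    upper <- integer(0)
    for (b in part3$balls) {
      inside <- labels[b$members] == concept
      if (all(inside)) lower <- c(lower, b$members)
      if (any(inside)) upper <- c(upper, b$members)
    }
    expect_equal(ap3$lower, sort(lower))
    expect_equal(ap3$upper, sort(upper))
    expect_true(all(ap3$lower %in% ap3$upper))
    expect_true(all(ap3$lower %in% which(labels == concept)))
    expect_true(all(which(labels == concept) %in% ap3$upper))
  }
})

test_that("positive region equals coverage and the summed lower approximations", {
  fx <- separated_clusters()
  expect_equal(positive_region_size(fx$values, fx$labels, 1:2), 10L)

  same <- matrix(0, 6, 2)
  expect_equal(positive_region_size(same, rep(c(1L, 2L), 3), 1:2), 0L)

  for (seed in 1:5) {
    set.seed(seed)
    n <- 25
    values <- matrix(sample(seq(0, 1, 0.2), n * 2, replace = TRUE), n, 2)
    labels <- sample(1:3, n, replace = TRUE)
    part <- generate_gb_partition(values, labels, 1:2)
    lower_sum <- sum(vapply(sort(unique(labels)), function(cc) {
      length(gb_approximate(part, labels, cc)$lower)
    }, integer(1)))
    expect_equal(positive_region_size(values, labels, 1:2), lower_sum)
    expect_equal(positive_region_size(values, labels, 1:2), gb_coverage(part))
  }
})

test_that("forward selection recovers a planted single-attribute signal", {
  tab <- planted_signal_table(n = 30, d_noise = 2, seed = 7)
  red <- gbrs_forward_select(tab, count_singletons = FALSE)
  expect_s3_class(red, "gbrs_reduct")
  expect_true(1L %in% red$selected)
  expect_false(any(2:3 %in% red$selected))

  # exhaustive enumeration over all non-empty subsets confirms {1} is a
  # maximal-coverage set no noise attribute improves on
  labels <- discretize_target(tab)
  v <- min_max_normalize(tab)$values
  cov_of <- function(B) positive_region_size(v, labels$labels, B,
                                             count_singletons = FALSE)
  subsets <- unlist(lapply(1:3, function(k) combn(3, k, simplify = FALSE)),
                    recursive = FALSE)
  covs <- vapply(subsets, cov_of, integer(1))
  expect_equal(cov_of(1L), max(covs))
})

test_that("forward selection handles single attributes and pure-noise pathology", {
  # single separable attribute: selected = {1} with full coverage
  x <- matrix(seq(0, 1, length.out = 12), 12, 1)
  tab <- sample_table(x, target = rep(c(10, 20, 30), each = 4))
  red <- gbrs_forward_select(tab, count_singletons = TRUE)
  expect_equal(red$selected, 1L)
  expect_equal(red$final_coverage, 12L)

  # all-noise attributes with literal singleton counting: coverage saturates
  # at n through singleton balls (the documented pathology)
  set.seed(99)
  noise_tab <- sample_table(matrix(rnorm(60), 20, 3), target = rnorm(20))
  lit <- gbrs_forward_select(noise_tab, count_singletons = TRUE)
  expect_equal(lit$final_coverage, 20L)
  expect_equal(lit$coverage_trace$coverage_after[1], 20L)
})

test_that("the retained-coverage trajectory is monotone and beats single attributes", {
  set.seed(13)
  n <- 40
  values <- cbind(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 2), n, 2))
  target <- values[, 1] * 2 + values[, 2] + rnorm(n, 0, 0.3)
  tab <- sample_table(values, target)
  red <- gbrs_forward_select(tab, count_singletons = FALSE)
  kept <- red$coverage_trace[red$coverage_trace$retained, ]
  if (nrow(kept) > 1) {
    expect_true(all(diff(kept$coverage_after) > 0))
  }
  expect_true(all(kept$coverage_after > kept$coverage_before))
  # final coverage at least matches every single attribute alone
  labels <- discretize_target(tab)
  v <- min_max_normalize(tab)$values
  singles <- vapply(1:4, function(a) {
    positive_region_size(v, labels$labels, a, count_singletons = FALSE)
  }, integer(1))
  expect_gte(red$final_coverage, max(singles))
})

test_that("reducts serialise to JSON with their trace", {
  tab <- planted_signal_table()
  red <- gbrs_forward_select(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_reduct(red, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$selected, red$selected)
  expect_equal(back$final_coverage, red$final_coverage)
  expect_equal(nrow(back$coverage_trace), nrow(red$coverage_trace))
})
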