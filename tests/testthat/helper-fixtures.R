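# Fixture builders shared across test files. All randomness is seeded at the
# call site so every test is reproducible in isolation.

# Two well-separated labelled clusters in 2-D: 5 samples near the origin,
# 5 near (10, 10), with a target that follows the cluster.
separated_clusters <- function(eps = 0.1, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(10, 0, eps), 5, 2)
  b <- matrix(rnorm(10, 10, eps), 5, 2)
  values <- rbind(a, b)
  colnames(values) <- c("u", "v")
  list(values = values,
       labels = rep(1:2, each = 5),
       table = sample_table(values, target = c(rep(1, 5), rep(100, 5))))
}

# A table whose class labels are carried by attribute 1 alone; the remaining
# attributes are i.i.d. noise.
planted_signal_table <- function(n = 30, d_noise = 2, seed = 7) {
  set.seed(seed)
  x1 <- runif(n)
  noise <- matrix(rnorm(n * d_noise), n, d_noise)
  values <- cbind(x1, noise)
  colnames(values) <- c("signal", paste0("noise", seq_len(d_noise)))
  # target = step function of attribute 1 so the tercile labels are exactly
  # determined by it, far apart so the steps survive discretisation
  target <- as.numeric(cut(x1, stats::quantile(x1, c(0, 1/3, 2/3, 1)),
                           include.lowest = TRUE)) * 100
  sample_table(values, target)
}

# Random small regression table.
random_table <- function(n = 20, d = 3, seed = 1) {
  set.seed(seed)
  values <- matrix(rnorm(n * d), n, d)
  sample_table(values, target = rnorm(n))
}

# Write a small CSV and return its path (tidied up by testthat).
write_fixture_csv <- function(lines, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  writeLines(lines, path)
  path
}
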