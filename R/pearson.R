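#' Population Pearson correlation coefficient
#'
#' Computed from population (1/n) moments: the mean, the population
#' covariance and the population standard deviations. The 1/n versus
#' 1/(n-1) distinction cancels in the ratio, but [pearson_stats()] exposes
#' the intermediate moments for inspection. The result is clamped to
#' `[-1, 1]` to absorb last-bit rounding on exactly collinear input.
#'
#' @param x,y numeric vectors of equal length `n >= 2`, each with nonzero
#'   variance.
#' @return The correlation in `[-1, 1]`; exactly `+1`/`-1` when
#'   `y = a*x + b` with `a > 0` / `a < 0`.
#' @export
pearson_r <- function(x, y) {
  pearson_stats(x, y)$rho
}

#' @rdname pearson_r
#' @return For `pearson_stats()`: a list with `mean_x`, `mean_y`, `cov`
#'   (population covariance), `sd_x`, `sd_y` (population standard
#'   deviations) and `rho`.
#' @export
pearson_stats <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (n < 2L || length(y) != n) {
    stop("x and y must have equal length of at least 2")
  }
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  dy <- y - my
  sd_x <- sqrt(mean(dx^2))
  sd_y <- sqrt(mean(dy^2))
  if (sd_x == 0 || sd_y == 0) {
    stop("undefined correlation: zero variance input")
  }
  rho <- mean(dx * dy) / (sd_x * sd_y)
  list(mean_x = mx, mean_y = my, cov = mean(dx * dy),
       sd_x = sd_x, sd_y = sd_y,
       rho = max(-1, min(1, rho)))
}

#' Rank condition attributes by correlation with the target
#'
#' Computes the Pearson coefficient of every condition attribute against the
#' decision attribute and orders attributes by descending absolute
#' correlation. Constant attributes are assigned a coefficient of 0 with a
#' warning; a constant target is an error.
#'
#' @param table a [sample_table()].
#' @return An object of class `correlation_ranking`: `coefficients` (named
#'   per-attribute rho) and `order` (attribute indices sorted by `|rho|`,
#'   strongest first; ties keep column order).
#' @export
rank_attributes <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  y <- table$target
  if (stats::var(y) == 0) stop("decision attribute has zero variance")
  d <- ncol(table$values)
  rho <- numeric(d)
  for (j in seq_len(d)) {
    x <- table$values[, j]
    if (max(x) == min(x)) {
      warning(sprintf("attribute '%s' is constant; correlation set to 0",
                      table$attribute_names[j]))
      rho[j] <- 0
    } else {
      rho[j] <- pearson_r(x, y)
    }
  }
  names(rho) <- table$attribute_names
  structure(list(coefficients = rho,
                 order = order(abs(rho), decreasing = TRUE)),
            class = "correlation_ranking")
}

#' @export
print.correlation_ranking <- function(x, ...) {
  cat("correlation_ranking (strongest first):\n")
  print(round(x$coefficients[x$order], 4))
  invisible(x)
}

#' Ranked-removal feature sweep scored by a regressor
#'
#' Implements the correlation-sweep selection strategy: attributes are ranked
#' by absolute correlation with the target, then evaluated on a sequence of
#' nested subsets of size `d, d-1, ..., 1` obtained by removing one attribute
#' at a time. Each subset is scored by cross-validated RMSE of the chosen
#' regressor -- for kNN, minimised over the `k` grid -- and the subset with
#' the lowest score wins (ties go to the smaller subset).
#'
#' By default the weakest attribute (smallest `|rho|`) is removed first, so
#' the size-`s` subset keeps the `s` strongest attributes.
#' `drop_order = "literal"` removes the strongest first instead.
#'
#' @param table a [sample_table()].
#' @param ranking optional [rank_attributes()] result; computed from `table`
#'   if missing.
#' @param regressor `"knn"` or `"mlp"`.
#' @param k_grid neighbour counts scored for kNN; default `1, 3, ..., 15`.
#' @param n_folds,seed cross-validation plan used for every subset (shared,
#'   so scores are comparable across sizes).
#' @param drop_order `"weakest"` (default) or `"literal"`.
#' @param mlp_config named list of overrides passed to [mlp_train()].
#' @return An object of class `pearson_sweep`: `grid` (matrix of CV RMSE,
#'   rows = feature counts `d..1`, columns = `k` values, or a single column
#'   for the MLP), `per_size_scores`, `subsets` (the nested subsets, named by
#'   size), `best_size`, `best_subset`, `best_k` (kNN only), `ranking`,
#'   `drop_order` and `regressor`.
#' @export
sweep_select <- function(table, ranking = NULL,
                         regressor = c("knn", "mlp"),
                         k_grid = c(1, 3, 5, 7, 9, 11, 13, 15),
                         n_folds = 5L, seed = 20240223,
                         drop_order = c("weakest", "literal"),
                         mlp_config = list()) {
  stopifnot(inherits(table, "sample_table"))
  regressor <- match.arg(regressor)
  drop_order <- match.arg(drop_order)
  if (is.null(ranking)) ranking <- rank_attributes(table)
  d <- ncol(table$values)
  sizes <- rev(seq_len(d))          # d, d-1, ..., 1
  subsets <- lapply(sizes, function(s) {
    if (drop_order == "weakest") sort(ranking$order[seq_len(s)])
    else sort(ranking$order[seq.int(d - s + 1L, d)])
  })
  names(subsets) <- as.character(sizes)
  folds <- make_folds(nrow(table$values), n_folds, seed)
  if (regressor == "knn") {
    k_grid <- as.integer(k_grid)
    grid <- matrix(NA_real_, nrow = length(sizes), ncol = length(k_grid),
                   dimnames = list(as.character(sizes), paste0("k=", k_grid)))
    for (i in seq_along(sizes)) {
      for (j in seq_along(k_grid)) {
        pred <- cv_oof_knn(table, subsets[[i]], k_grid[j], folds)
        grid[i, j] <- sqrt(mean((pred - table$target)^2))
      }
    }
    per_size <- apply(grid, 1, min)
  } else {
    grid <- matrix(NA_real_, nrow = length(sizes), ncol = 1L,
                   dimnames = list(as.character(sizes), "rmse"))
    for (i in seq_along(sizes)) {
      pred <- cv_oof_mlp(table, subsets[[i]], folds, mlp_config, seed)
      grid[i, 1] <- sqrt(mean((pred - table$target)^2))
    }
    per_size <- grid[, 1]
  }
  # prefer the most parsimonious subset among score ties
  best_i <- length(per_size) + 1L - which.min(rev(per_size))
  best <- list(size = sizes[best_i], subset = subsets[[best_i]])
  structure(list(grid = grid, per_size_scores = per_size, subsets = subsets,
                 best_size = best$size, best_subset = best$subset,
                 best_k = if (regressor == "knn")
                   k_grid[which.min(grid[best_i, ])] else NULL,
                 ranking = ranking, drop_order = drop_order,
                 regressor = regressor, n_folds = n_folds, seed = seed),
            class = "pearson_sweep")
}

#' @export
print.pearson_sweep <- function(x, ...) {
  cat(sprintf("pearson_sweep (%s, drop %s first): best size %d",
              x$regressor, x$drop_order, x$best_size))
  if (!is.null(x$best_k)) cat(sprintf(" at k=%d", x$best_k))
  cat(sprintf(", CV RMSE %.4g\n", min(x$per_size_scores)))
  cat("best subset:", paste(x$best_subset, collapse = ", "), "\n")
  invisible(x)
}
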