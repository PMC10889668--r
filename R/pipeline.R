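# Cross-validated scoring and the method-comparison pipelines
# (kNN, PK, GBRSK, BP, PBP, GBRSBP).

# Pooled out-of-fold kNN predictions on an attribute subset.
cv_oof_knn <- function(table, attrs, k, folds) {
  n <- nrow(table$values)
  pred <- numeric(n)
  for (f in seq_len(folds$n_folds)) {
    te <- folds$fold_assignments == f
    fit <- knn_fit(table$values[!te, attrs, drop = FALSE],
                   table$target[!te], k = k)
    pred[te] <- predict(fit, table$values[te, attrs, drop = FALSE])
  }
  pred
}

# Pooled out-of-fold MLP predictions on an attribute subset.
cv_oof_mlp <- function(table, attrs, folds, mlp_config, seed) {
  n <- nrow(table$values)
  pred <- numeric(n)
  for (f in seq_len(folds$n_folds)) {
    te <- folds$fold_assignments == f
    args <- c(list(x = table$values[!te, attrs, drop = FALSE],
                   y = table$target[!te],
                   seed = fold_seed(seed, f)),
              mlp_config)
    fit <- do.call(mlp_train, args)
    pred[te] <- predict(fit, table$values[te, attrs, drop = FALSE])
  }
  pred
}

# Derive a per-fold seed that stays inside 32-bit integer range.
fold_seed <- function(seed, f) {
  as.integer((as.numeric(seed) + 7919 * f) %% 2147483629)
}

#' Leakage-free cross-validated score of a selection + regression pipeline
#'
#' Runs feature selection inside each training fold (held-out targets are
#' never inspected), fits the regressor on the selected attributes, predicts
#' the held-out fold, and pools all out-of-fold predictions into one
#' [compute_metrics()] report. Deterministic for a fixed seed.
#'
#' @param table a [sample_table()].
#' @param selector `"none"` (all attributes), `"pearson"` (ranked-removal
#'   sweep, [sweep_select()]) or `"gbrs"` ([gbrs_forward_select()]; an empty
#'   reduct falls back to all attributes).
#' @param regressor `"knn"`, `"mlp"`, or `"mean"` (constant training-fold
#'   mean, a baseline).
#' @param k neighbour count for the kNN regressor.
#' @param n_folds,seed the fold plan ([make_folds()]).
#' @param q,purity_threshold,count_singletons GBRS selection settings.
#' @param drop_order,k_grid Pearson sweep settings (the sweep scores subsets
#'   with an inner cross-validation on the training fold).
#' @param mlp_config named list of [mlp_train()] overrides.
#' @return A `metric_report` (also class `cv_score`) with extra fields
#'   `fold_subsets` (attributes selected in each training fold) and
#'   `predictions` (pooled out-of-fold predictions).
#' @export
cross_validated_score <- function(table,
                                  selector = c("none", "pearson", "gbrs"),
                                  regressor = c("knn", "mlp", "mean"),
                                  k = 3L, n_folds = 5L, seed = 20240223,
                                  q = 3L, purity_threshold = 1,
                                  count_singletons = FALSE,
                                  drop_order = "weakest",
                                  k_grid = c(1, 3, 5, 7, 9, 11, 13, 15),
                                  mlp_config = list()) {
  stopifnot(inherits(table, "sample_table"))
  selector <- match.arg(selector)
  regressor <- match.arg(regressor)
  n <- nrow(table$values)
  d <- ncol(table$values)
  folds <- make_folds(n, n_folds, seed)
  pred <- numeric(n)
  fold_subsets <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- folds$fold_assignments == f
    tr <- table_rows(table, !te)
    attrs <- switch(selector,
      none = seq_len(d),
      pearson = sweep_select(tr,
                             regressor = if (regressor == "mlp") "mlp" else "knn",
                             k_grid = k_grid,
                             n_folds = min(n_folds, nrow(tr$values) - 1L),
                             seed = fold_seed(seed, f),
                             drop_order = drop_order,
                             mlp_config = mlp_config)$best_subset,
      gbrs = {
        sel <- gbrs_forward_select(tr, q = q,
                                   purity_threshold = purity_threshold,
                                   count_singletons = count_singletons)$selected
        if (length(sel) == 0L) seq_len(d) else sort(sel)
      })
    fold_subsets[[f]] <- attrs
    xtr <- tr$values[, attrs, drop = FALSE]
    xte <- table$values[te, attrs, drop = FALSE]
    pred[te] <- switch(regressor,
      knn = predict(knn_fit(xtr, tr$target, k = k), xte),
      mlp = predict(do.call(mlp_train,
                            c(list(x = xtr, y = tr$target,
                                   seed = fold_seed(seed, f)), mlp_config)),
                    xte),
      mean = rep(mean(tr$target), sum(te)))
  }
  rep <- compute_metrics(table$target, pred)
  rep$fold_subsets <- fold_subsets
  rep$predictions <- pred
  class(rep) <- c("cv_score", "metric_report")
  rep
}

#' Run one of the six prediction pipelines
#'
#' Evaluates a full method by cross-validation with per-fold feature
#' selection:
#' \describe{
#'   \item{knn / bp}{no selection, all condition attributes.}
#'   \item{pk / pbp}{Pearson ranked-removal sweep: every nested subset size
#'     `d..1` (ranked within each training fold) is scored, giving the
#'     familiar feature-count by `k` error grid for kNN or a per-size column
#'     for the network.}
#'   \item{gbrsk / gbrsbp}{granular-ball rough set forward reduction within
#'     each training fold, then regression on the reduct.}
#' }
#' kNN-family methods produce one column of pooled out-of-fold RMSE per `k`
#' in `k_grid`; BP-family methods a single RMSE column. The best cell (ties:
#' fewest features, then smallest `k`) is identified and its pooled
#' predictions summarised with all four metrics.
#'
#' @inheritParams cross_validated_score
#' @param method one of `"knn"`, `"pk"`, `"gbrsk"`, `"bp"`, `"pbp"`,
#'   `"gbrsbp"`.
#' @return An object of class `experiment_grid`: `method`, `scores` (RMSE
#'   matrix, rows = feature sets, columns = `k` values or `"rmse"`), `best`
#'   (row/column indices, feature-set label, `k`, RMSE), `metrics`
#'   (`metric_report` at the best cell), `predictions` (pooled predictions at
#'   the best cell), `fold_subsets`, `k_grid`, `n_folds`, `seed`.
#' @export
run_method <- function(table,
                       method = c("knn", "pk", "gbrsk", "bp", "pbp", "gbrsbp"),
                       k_grid = c(1, 3, 5, 7, 9, 11, 13, 15),
                       n_folds = 5L, seed = 20240223, q = 3L,
                       purity_threshold = 1, count_singletons = FALSE,
                       drop_order = "weakest", mlp_config = list()) {
  stopifnot(inherits(table, "sample_table"))
  method <- match.arg(method)
  n <- nrow(table$values)
  d <- ncol(table$values)
  folds <- make_folds(n, n_folds, seed)
  k_grid <- as.integer(k_grid)

  # Per-fold feature sets, one entry per grid row.
  fold_subsets <- vector("list", folds$n_folds)
  for (f in seq_len(folds$n_folds)) {
    tr <- table_rows(table, folds$fold_assignments != f)
    fold_subsets[[f]] <- switch(method,
      knn = ,
      bp = list(all = seq_len(d)),
      pk = ,
      pbp = {
        rk <- rank_attributes(tr)
        sizes <- rev(seq_len(d))
        subs <- lapply(sizes, function(s) {
          if (drop_order == "weakest") sort(rk$order[seq_len(s)])
          else sort(rk$order[seq.int(d - s + 1L, d)])
        })
        names(subs) <- as.character(sizes)
        subs
      },
      gbrsk = ,
      gbrsbp = {
        sel <- gbrs_forward_select(tr, q = q,
                                   purity_threshold = purity_threshold,
                                   count_singletons = count_singletons)$selected
        list(reduct = if (length(sel) == 0L) seq_len(d) else sort(sel))
      })
  }

  row_keys <- names(fold_subsets[[1L]])
  knn_family <- method %in% c("knn", "pk", "gbrsk")
  col_keys <- if (knn_family) paste0("k=", k_grid) else "rmse"
  scores <- matrix(NA_real_, length(row_keys), length(col_keys),
                   dimnames = list(row_keys, col_keys))
  preds <- vector("list", length(scores))
  dim(preds) <- dim(scores)
  for (ri in seq_along(row_keys)) {
    for (ci in seq_along(col_keys)) {
      pred <- numeric(n)
      for (f in seq_len(folds$n_folds)) {
        te <- folds$fold_assignments == f
        attrs <- fold_subsets[[f]][[ri]]
        xtr <- table$values[!te, attrs, drop = FALSE]
        ytr <- table$target[!te]
        xte <- table$values[te, attrs, drop = FALSE]
        pred[te] <- if (knn_family) {
          predict(knn_fit(xtr, ytr, k = k_grid[ci]), xte)
        } else {
          predict(do.call(mlp_train,
                          c(list(x = xtr, y = ytr, seed = fold_seed(seed, f)),
                            mlp_config)),
                  xte)
        }
      }
      scores[ri, ci] <- sqrt(mean((pred - table$target)^2))
      preds[[ri, ci]] <- pred
    }
  }

  cand <- which(scores == min(scores), arr.ind = TRUE)
  cand <- cand[order(-cand[, 1], cand[, 2]), , drop = FALSE]  # fewest features, then smallest k
  ri <- cand[1, 1]
  ci <- cand[1, 2]
  best <- list(row_index = ri, col_index = ci,
               feature_set = row_keys[ri],
               k = if (knn_family) k_grid[ci] else NULL,
               rmse = scores[ri, ci])
  structure(list(method = method, scores = scores, best = best,
                 metrics = compute_metrics(table$target, preds[[ri, ci]]),
                 predictions = preds[[ri, ci]],
                 fold_subsets = fold_subsets,
                 k_grid = if (knn_family) k_grid else NULL,
                 n_folds = folds$n_folds, seed = seed),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf("experiment_grid [%s]: best RMSE %.6g (features: %s%s)\n",
              toupper(x$method), x$best$rmse, x$best$feature_set,
              if (!is.null(x$best$k)) sprintf(", k=%d", x$best$k) else ""))
  print(round(x$scores, 2))
  invisible(x)
}

#' Write a result report as CSV
#'
#' Accepts an `experiment_grid` (rows = feature counts in descending order,
#' columns = `k` values or RMSE), a single `metric_report` (columns RMSE,
#' MAE, MAPE, R2), or a named list of `metric_report`s (one row per method).
#' The best cell / best-RMSE row is flagged with a `*`, mirroring the
#' bold-face convention of comparison tables.
#'
#' @param x the object to report.
#' @param path output CSV path.
#' @param integer_mode round errors to whole numbers for display parity with
#'   integer-reported tables (default `FALSE`: six significant digits).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, integer_mode = FALSE) {
  fmt <- function(v) {
    if (integer_mode) sprintf("%.0f", v) else sprintf("%.6g", v)
  }
  if (inherits(x, "experiment_grid")) {
    sc <- x$scores
    chr <- matrix(fmt(sc), nrow(sc), ncol(sc), dimnames = dimnames(sc))
    ri <- x$best$row_index
    ci <- x$best$col_index
    chr[ri, ci] <- paste0(chr[ri, ci], "*")
    df <- data.frame(Features = rownames(sc), chr, check.names = FALSE)
  } else if (inherits(x, "metric_report")) {
    df <- metric_row(x, fmt)
  } else if (is.list(x) && length(x) > 0 &&
             all(vapply(x, inherits, logical(1), "metric_report"))) {
    rows <- do.call(rbind, lapply(x, metric_row, fmt = fmt))
    best <- which.min(vapply(x, function(r) r$rmse, numeric(1)))
    rows$RMSE[best] <- paste0(rows$RMSE[best], "*")
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("method", seq_along(x))
    df <- cbind(Method = nm, rows)
  } else {
    stop("nothing to report: expected an experiment_grid or metric_report(s)")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

metric_row <- function(r, fmt) {
  data.frame(RMSE = fmt(r$rmse), MAE = fmt(r$mae), MAPE = fmt(r$mape),
             R2 = fmt(r$r2), n = r$n_evaluated,
             stringsAsFactors = FALSE)
}
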