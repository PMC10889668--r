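#' Fit a k-nearest-neighbour regressor
#'
#' Stores the training samples (min-max normalised by default, with the
#' scaling parameters kept so queries are rescaled identically) and the
#' neighbour count. Prediction is the unweighted mean of the `k` training
#' targets nearest in Euclidean distance over the condition attributes;
#' distance ties are broken by ascending training-sample index.
#'
#' @param x numeric matrix of training condition attributes (`m x d`).
#' @param y numeric vector of training targets, length `m`.
#' @param k neighbour count, `1 <= k <= m`.
#' @param normalize min-max scale the attributes (default `TRUE`).
#' @return An object of class `knn_model`.
#' @export
knn_fit <- function(x, y, k = 3L, normalize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  k <- as.integer(k)
  m <- nrow(x)
  stopifnot(length(y) == m)
  if (k < 1L) stop("k must be at least 1")
  if (k > m) stop("k (", k, ") exceeds the number of training samples (", m, ")")
  scaling <- NULL
  if (normalize) {
    mins <- apply(x, 2, min)
    scaling <- list(min = mins, range = apply(x, 2, max) - mins)
    x <- scale_matrix(x, scaling)
  }
  structure(list(x = x, y = y, k = k, scaling = scaling),
            class = "knn_model")
}

scale_matrix <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  div <- ifelse(scaling$range > 0, scaling$range, 1)
  out <- sweep(sweep(x, 2, scaling$min, "-"), 2, div, "/")
  out[, scaling$range == 0] <- 0
  out
}

#' Predict with a fitted kNN regressor
#'
#' @param object a `knn_model` from [knn_fit()].
#' @param newdata numeric matrix of queries (`q x d`), or a single length-`d`
#'   vector.
#' @param ... unused.
#' @return Numeric vector of predictions, each the mean of the `k` nearest
#'   training targets.
#' @export
predict.knn_model <- function(object, newdata, ...) {
  q <- newdata
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  q <- as.matrix(q)
  if (ncol(q) != ncol(object$x)) {
    stop("query has ", ncol(q), " attributes; model expects ", ncol(object$x))
  }
  q <- scale_matrix(q, object$scaling)
  k <- object$k
  apply(q, 1, function(row) {
    d2 <- row_dist2(object$x, row)
    ord <- order(d2, seq_along(d2))        # ties -> ascending training index
    mean(object$y[ord[seq_len(k)]])
  })
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("knn_model: k=%d, %d training samples, %d attributes%s\n",
              x$k, nrow(x$x), ncol(x$x),
              if (is.null(x$scaling)) "" else " (min-max scaled)"))
  invisible(x)
}
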