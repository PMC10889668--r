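#' Forward pass of a multi-layer perceptron
#'
#' Layer-by-layer affine-then-activation composition: every layer computes
#' `z = a %*% W + b`; hidden layers apply the logistic activation and the
#' output layer is linear. Exposed separately so the network function can be
#' evaluated on arbitrary weights.
#'
#' @param weights list of layers, each a list with matrix `W`
#'   (`in x out`) and bias vector `b` (length `out`).
#' @param x numeric input matrix (`n x d`), or a single length-`d` vector.
#' @return Numeric matrix of outputs (`n x out_L`).
#' @export
mlp_forward <- function(weights, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  a <- as.matrix(x)
  L <- length(weights)
  for (l in seq_len(L)) {
    z <- a %*% weights[[l]]$W +
      matrix(weights[[l]]$b, nrow(a), length(weights[[l]]$b), byrow = TRUE)
    a <- if (l < L) stats::plogis(z) else z
  }
  a
}

#' Mean-squared-error loss of a network on a data set
#'
#' @inheritParams mlp_forward
#' @param y numeric target vector.
#' @return Scalar mean squared error of the network outputs against `y`.
#' @export
mlp_loss <- function(weights, x, y) {
  mean((drop(mlp_forward(weights, x)) - y)^2)
}

#' Analytic gradient of the MSE loss by back-propagation
#'
#' Returns the exact gradient of [mlp_loss()] with respect to every weight
#' and bias, computed by propagating the output error backwards through the
#' logistic layers. Verified in the test suite against central finite
#' differences.
#'
#' @inheritParams mlp_loss
#' @return A list shaped like `weights` holding the partial derivatives.
#' @export
mlp_gradient <- function(weights, x, y) {
  mlp_loss_grad(weights, x, y)$gradient
}

# Shared forward+backward pass; returns loss and gradient in one sweep.
mlp_loss_grad <- function(weights, x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  n <- nrow(x)
  L <- length(weights)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- x
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% weights[[l]]$W +
      matrix(weights[[l]]$b, n, length(weights[[l]]$b), byrow = TRUE)
    acts[[l + 1L]] <- if (l < L) stats::plogis(z) else z
  }
  out <- acts[[L + 1L]]
  err <- out - matrix(y, n, ncol(out))
  loss <- mean(err^2)
  grad <- vector("list", L)
  delta <- 2 * err / (n * ncol(out))
  for (l in rev(seq_len(L))) {
    grad[[l]] <- list(W = crossprod(acts[[l]], delta),
                      b = colSums(delta))
    if (l > 1L) {
      a_prev <- acts[[l]]
      delta <- (delta %*% t(weights[[l]]$W)) * a_prev * (1 - a_prev)
    }
  }
  list(loss = loss, gradient = grad)
}

#' Initialise network weights
#'
#' Uniform initialisation on `[-1, 1]/sqrt(fan_in)` per layer, drawn under a
#' fixed seed so training is reproducible bit-for-bit.
#'
#' @param layer_sizes integer vector `[d, h1, ..., 1]`.
#' @param seed integer seed.
#' @return A weight list usable with [mlp_forward()].
#' @export
mlp_init <- function(layer_sizes, seed) {
  stopifnot(length(layer_sizes) >= 2L)
  with_seed(seed, {
    lapply(seq_len(length(layer_sizes) - 1L), function(l) {
      fan_in <- layer_sizes[l]
      fan_out <- layer_sizes[l + 1L]
      list(W = matrix(stats::runif(fan_in * fan_out, -1, 1) / sqrt(fan_in),
                      fan_in, fan_out),
           b = rep(0, fan_out))
    })
  })
}

#' Train a back-propagation network by full-batch gradient descent
#'
#' A multi-layer feed-forward network (one logistic hidden layer by default,
#' linear output) trained by plain steepest descent on the mean squared
#' error, the classic error back-propagation scheme. Inputs are min-max
#' scaled and the target is standardised internally (both undone at
#' prediction time) so the fixed learning rate is usable across the heavy
#' chlorophyll scales. Training is deterministic for a fixed seed.
#'
#' @param x numeric training matrix (`n x d`).
#' @param y numeric target vector.
#' @param hidden integer vector of hidden-layer widths; default one layer of
#'   `max(8, 2d)` units.
#' @param learning_rate gradient-descent step size (default 0.01).
#' @param epochs number of full-batch epochs (default 2000). `epochs = 0`
#'   returns the initialised network untouched.
#' @param seed seed for the weight initialisation.
#' @param normalize min-max scale the inputs (default `TRUE`).
#' @return An object of class `mlp_model`: `weights`, `layer_sizes`,
#'   scaling parameters, `loss_trace` (per-epoch training MSE in the
#'   standardised space) and the training configuration.
#' @export
mlp_train <- function(x, y, hidden = NULL, learning_rate = 0.01,
                      epochs = 2000L, seed = 1L, normalize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (n < 2L) stop("need at least 2 training samples")
  d <- ncol(x)
  if (is.null(hidden)) hidden <- max(8L, 2L * d)
  scaling <- NULL
  if (normalize) {
    mins <- apply(x, 2, min)
    scaling <- list(min = mins, range = apply(x, 2, max) - mins)
    x <- scale_matrix(x, scaling)
  }
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  ys <- (y - y_center) / y_scale
  layer_sizes <- c(d, as.integer(hidden), 1L)
  weights <- mlp_init(layer_sizes, seed)
  loss_trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    lg <- mlp_loss_grad(weights, x, ys)
    if (!is.finite(lg$loss)) {
      stop(sprintf("non-finite training loss at epoch %d; lower the learning rate", e))
    }
    loss_trace[e] <- lg$loss
    for (l in seq_along(weights)) {
      weights[[l]]$W <- weights[[l]]$W - learning_rate * lg$gradient[[l]]$W
      weights[[l]]$b <- weights[[l]]$b - learning_rate * lg$gradient[[l]]$b
    }
  }
  structure(list(weights = weights, layer_sizes = layer_sizes,
                 scaling = scaling, y_center = y_center, y_scale = y_scale,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), loss_trace = loss_trace),
            class = "mlp_model")
}

#' Predict with a trained back-propagation network
#'
#' @param object an `mlp_model` from [mlp_train()].
#' @param newdata numeric matrix of queries, or a single vector.
#' @param ... unused.
#' @return Numeric vector of predictions on the original target scale.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  q <- newdata
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  q <- scale_matrix(as.matrix(q), object$scaling)
  drop(mlp_forward(object$weights, q)) * object$y_scale + object$y_center
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: layers [%s], lr %g, %d epochs, final loss %.4g\n",
              paste(x$layer_sizes, collapse = ", "), x$learning_rate,
              x$epochs,
              if (x$epochs > 0) x$loss_trace[x$epochs] else NA))
  invisible(x)
}

#' Save or load a fitted model as JSON
#'
#' Serialises `knn_model` and `mlp_model` objects (weights, training data,
#' scaling parameters, hyperparameters) with full numeric precision.
#'
#' @param model a `knn_model` or `mlp_model`.
#' @param path file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the restored model.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1]
  if (!cls %in% c("knn_model", "mlp_model")) {
    stop("unsupported model class: ", cls)
  }
  payload <- unclass(model)
  payload$.class <- cls
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "knn_model")) {
    obj$x <- as.matrix(obj$x)
    obj$k <- as.integer(obj$k)
    if (!is.null(obj$scaling)) obj$scaling <- lapply(obj$scaling, as.numeric)
  } else if (identical(cls, "mlp_model")) {
    obj$weights <- lapply(obj$weights, function(l) {
      list(W = as.matrix(l$W), b = as.numeric(l$b))
    })
    if (!is.null(obj$scaling)) obj$scaling <- lapply(obj$scaling, as.numeric)
  } else {
    stop("not a serialised hydrogb model: ", path)
  }
  structure(obj, class = cls)
}
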