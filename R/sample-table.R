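#' Construct a sample table
#'
#' A `sample_table` is the information system every stage of the toolkit
#' operates on: an `n x d` matrix of continuous condition attributes (water
#' level, flow, chemistry, ...) plus one continuous decision attribute, here
#' typically the chlorophyll quantity of a single algal phylum.
#'
#' @param values numeric matrix (or coercible data frame), `n` samples by `d`
#'   condition attributes. No missing values are allowed.
#' @param target numeric vector of length `n`: the decision attribute.
#' @param attribute_names optional character vector of `d` attribute labels;
#'   defaults to the column names of `values`.
#' @param sample_ids optional character vector of `n` sample labels.
#'
#' @return An object of class `sample_table` with fields `values`, `target`,
#'   `attribute_names` and `sample_ids`.
#' @seealso [read_sample_table()], [min_max_normalize()], [discretize_target()]
#' @export
sample_table <- function(values, target, attribute_names = NULL,
                         sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  target <- as.numeric(target)
  n <- nrow(values)
  d <- ncol(values)
  if (n < 1L || d < 1L) {
    stop("a sample table needs at least one sample and one condition attribute")
  }
  if (length(target) != n) {
    stop("target length (", length(target), ") does not match sample count (",
         n, ")")
  }
  if (anyNA(values) || anyNA(target)) {
    stop("sample tables must not contain missing values; drop or impute first")
  }
  if (is.null(attribute_names)) {
    attribute_names <- colnames(values)
    if (is.null(attribute_names)) attribute_names <- paste0("a", seq_len(d))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  }
  stopifnot(length(attribute_names) == d, length(sample_ids) == n)
  dimnames(values) <- list(NULL, attribute_names)
  structure(
    list(values = values, target = target,
         attribute_names = attribute_names,
         sample_ids = as.character(sample_ids)),
    class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("sample_table: %d samples x %d condition attributes\n",
              nrow(x$values), ncol(x$values)))
  cat("attributes:", paste(utils::head(x$attribute_names, 8L), collapse = ", "),
      if (length(x$attribute_names) > 8L) "..." else "", "\n")
  cat(sprintf("target: range [%.4g, %.4g]\n",
              min(x$target), max(x$target)))
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$values)

#' Read a monitoring table from CSV
#'
#' Reads a header-bearing delimited file, takes `target_column` as the
#' decision attribute and every other numeric column as a condition
#' attribute. Rows with missing or non-numeric cells are dropped with a
#' warning stating how many were lost; entirely non-numeric columns (dates,
#' station names) are ignored.
#'
#' @param path path to a CSV file (RFC-4180, header row).
#' @param target_column name of the decision-attribute column.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path, target_column) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!target_column %in% names(raw)) {
    stop("target column '", target_column, "' not present in ", path)
  }
  num <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  target <- num[[target_column]]
  if (all(is.na(target))) {
    stop("target column '", target_column, "' contains no numeric values")
  }
  cond <- num[setdiff(names(num), target_column)]
  keep <- vapply(cond, function(col) any(!is.na(col)), logical(1))
  cond <- cond[keep]
  if (length(cond) == 0L) stop("no numeric condition attributes found")
  mat <- do.call(cbind, cond)
  ok <- !is.na(target) & rowSums(is.na(mat)) == 0L
  dropped <- sum(!ok)
  if (dropped > 0L) {
    warning(sprintf("dropped %d row(s) with missing or non-numeric cells",
                    dropped))
  }
  if (!any(ok)) stop("zero usable rows after dropping incomplete records")
  sample_table(mat[ok, , drop = FALSE], target[ok],
               attribute_names = names(cond),
               sample_ids = as.character(which(ok)))
}

#' Write a sample table to CSV
#'
#' Values are serialised with 17 significant digits so that a write/read
#' round trip reproduces the table to full double precision.
#'
#' @param table a [sample_table()].
#' @param path output file path.
#' @param target_column name used for the decision-attribute column.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path, target_column = "target") {
  stopifnot(inherits(table, "sample_table"))
  cols <- c(
    stats::setNames(
      lapply(seq_len(ncol(table$values)),
             function(j) sprintf("%.17g", table$values[, j])),
      table$attribute_names),
    stats::setNames(list(sprintf("%.17g", table$target)), target_column))
  df <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max normalisation of condition attributes
#'
#' Rescales each condition attribute to `[0, 1]`. Constant attributes map to
#' zero everywhere. The scaling parameters (per-attribute minimum and range)
#' are attached to the result, and can be passed back in so that test samples
#' are rescaled with training-set parameters; values outside the training
#' range then legitimately fall outside `[0, 1]`. The decision attribute is
#' never rescaled.
#'
#' @param table a [sample_table()].
#' @param scaling optional scaling parameters from a previous call (the
#'   `"scaling"` attribute of a normalised table, a list with `min` and
#'   `range`).
#' @return A normalised [sample_table()] carrying a `"scaling"` attribute.
#' @export
min_max_normalize <- function(table, scaling = NULL) {
  stopifnot(inherits(table, "sample_table"))
  v <- table$values
  if (is.null(scaling)) {
    mins <- apply(v, 2, min)
    scaling <- list(min = mins, range = apply(v, 2, max) - mins)
  }
  div <- ifelse(scaling$range > 0, scaling$range, 1)
  out <- sweep(sweep(v, 2, scaling$min, "-"), 2, div, "/")
  out[, scaling$range == 0] <- 0
  res <- sample_table(out, table$target, table$attribute_names,
                      table$sample_ids)
  attr(res, "scaling") <- scaling
  res
}

#' Quantile discretisation of the decision attribute
#'
#' The granular-ball rough set machinery needs class labels for ball purity,
#' but chlorophyll quantity is continuous; this helper bins the target into
#' `q` quantile classes. Values falling exactly on a bin edge go to the lower
#' bin. The labels are used only inside attribute reduction, never for
#' regression.
#'
#' @param target a [sample_table()] or a numeric vector.
#' @param q number of bins (default 3). If the target has fewer distinct
#'   values than `q`, the bin count is reduced with a warning.
#' @return An object of class `discretized_target`: `labels` (integer codes
#'   `1..q`), `bin_edges` (the `q - 1` inner thresholds) and `q`.
#' @export
discretize_target <- function(target, q = 3L) {
  if (inherits(target, "sample_table")) target <- target$target
  target <- as.numeric(target)
  q <- as.integer(q)
  if (q < 2L) stop("q must be at least 2")
  n_distinct <- length(unique(target))
  if (n_distinct < q) {
    warning(sprintf("target has only %d distinct value(s); reducing q from %d",
                    n_distinct, q))
    q <- max(1L, n_distinct)
  }
  if (q == 1L) {
    return(structure(list(labels = rep(1L, length(target)),
                          bin_edges = numeric(0), q = 1L),
                     class = "discretized_target"))
  }
  edges <- stats::quantile(target, probs = seq_len(q - 1L) / q,
                           type = 7, names = FALSE)
  edges <- unique(edges)
  if (length(edges) + 1L < q) {
    warning(sprintf("tied quantiles collapse %d bin(s)",
                    q - length(edges) - 1L))
    q <- length(edges) + 1L
  }
  labels <- findInterval(target, edges, left.open = TRUE) + 1L
  structure(list(labels = labels, bin_edges = edges, q = q),
            class = "discretized_target")
}

#' @export
print.discretized_target <- function(x, ...) {
  cat(sprintf("discretized_target: %d samples in %d class(es)\n",
              length(x$labels), x$q))
  print(table(x$labels))
  invisible(x)
}

#' Balanced fold assignments for cross-validation
#'
#' @param n sample count.
#' @param n_folds number of folds, between 2 and `n`.
#' @param seed integer seed; the assignment is deterministic given the seed
#'   and does not disturb the caller's RNG stream.
#' @return An object of class `fold_plan`: `fold_assignments` (length-`n`
#'   integers in `1..n_folds`, fold sizes differing by at most one),
#'   `n_folds` and `seed`.
#' @export
make_folds <- function(n, n_folds, seed) {
  n <- as.integer(n)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (n_folds > n) stop("n_folds (", n_folds, ") exceeds sample count (", n, ")")
  assignments <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  structure(list(fold_assignments = assignments, n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

# Subset the rows of a sample table (internal).
table_rows <- function(table, idx) {
  sample_table(table$values[idx, , drop = FALSE], table$target[idx],
               table$attribute_names, table$sample_ids[idx])
}
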