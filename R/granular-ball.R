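#' Center and radius of a granular ball
#'
#' A granular ball summarises a set of samples by two quantities: its center
#' (the arithmetic mean of the member coordinates) and its radius (the mean
#' Euclidean distance of the members to the center). A singleton ball has
#' radius zero.
#'
#' @param points numeric matrix, one row per member sample, columns restricted
#'   to the attribute subset under consideration.
#' @return A list with `center` (numeric vector) and `radius` (non-negative
#'   scalar).
#' @export
gb_center_radius <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("cannot summarise an empty point set")
  center <- colMeans(points)
  radius <- mean(sqrt(row_dist2(points, center)))
  list(center = center, radius = radius)
}

# Build one ball over `members` (row indices into X) with purity bookkeeping.
new_ball <- function(members, X, labels, splittable = TRUE) {
  cr <- gb_center_radius(X[members, , drop = FALSE])
  counts <- table(labels[members])
  maj <- which.max(counts)                 # ties resolve to the smallest label
  list(center = cr$center,
       radius = cr$radius,
       members = members,
       majority_label = as.integer(names(counts)[maj]),
       purity = as.numeric(counts[maj]) / length(members),
       splittable = splittable)
}

#' Split a granular ball in two
#'
#' Partitions the members of an impure ball into two child balls with a
#' deterministic 2-means step: the two members farthest apart seed the
#' centers (ties resolved by lowest member index), points are assigned to the
#' nearer center (ties to the first), and centers are recomputed until the
#' assignment is stable. Balls whose member coordinates are all identical
#' cannot be split and are returned unchanged with `splittable = FALSE`.
#'
#' @param ball a ball as produced by [generate_gb_partition()] (a list with a
#'   `members` field).
#' @param X numeric matrix of coordinates on the attribute subset, indexed by
#'   the ball's `members`.
#' @param labels integer class labels for all samples (used to recompute the
#'   children's purity).
#' @return A list of two child balls, or a list containing the single
#'   original ball flagged unsplittable.
#' @export
gb_split_ball <- function(ball, X, labels) {
  members <- ball$members
  if (length(members) < 2L) stop("a ball needs at least 2 members to split")
  pts <- X[members, , drop = FALSE]
  D <- as.matrix(stats::dist(pts))
  if (max(D) == 0) {
    ball$splittable <- FALSE
    return(list(ball))
  }
  hit <- which(D == max(D), arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  c1 <- pts[hit[1, 1], ]
  c2 <- pts[hit[1, 2], ]
  assign <- integer(nrow(pts))
  for (it in seq_len(100L)) {
    a <- ifelse(row_dist2(pts, c1) <= row_dist2(pts, c2), 1L, 2L)
    if (identical(a, assign)) break
    if (!any(a == 1L) || !any(a == 2L)) break   # keep previous assignment
    assign <- a
    c1 <- colMeans(pts[assign == 1L, , drop = FALSE])
    c2 <- colMeans(pts[assign == 2L, , drop = FALSE])
  }
  list(new_ball(members[assign == 1L], X, labels),
       new_ball(members[assign == 2L], X, labels))
}

#' Generate a purity-driven granular-ball partition
#'
#' Starts from a single ball covering all samples and repeatedly splits any
#' ball whose purity (fraction of members carrying the majority class label)
#' is below `purity_threshold` and whose size exceeds `min_size`, until no
#' ball is splittable. The resulting balls partition the sample set: every
#' sample belongs to exactly one ball by construction (membership is
#' inherited from the splitting process, not re-derived from the geometric
#' radius test, which mean-distance radii would leave incomplete).
#'
#' The procedure is fully deterministic: child centers are seeded from the
#' farthest member pair, so repeated calls on the same inputs yield identical
#' partitions. `seed` is accepted for interface symmetry with the stochastic
#' stages but has no effect.
#'
#' @param values numeric matrix of condition attributes (normalised values
#'   recommended; distances are Euclidean).
#' @param labels integer class labels (e.g. from [discretize_target()]), or a
#'   `discretized_target`.
#' @param attributes integer indices of the attribute subset B inducing the
#'   partition.
#' @param purity_threshold minimum purity at which a ball stops splitting, in
#'   `(0, 1]`; default 1 (strict positive region).
#' @param min_size balls at or below this size are never split; default 1
#'   (singletons allowed).
#' @param seed ignored; see Details.
#' @return An object of class `gb_partition`: `balls` (list of balls with
#'   `center`, `radius`, `members`, `majority_label`, `purity`,
#'   `splittable`), `attribute_subset`, `purity_threshold`, `n` and
#'   `coverage` (see [gb_coverage()]).
#' @export
generate_gb_partition <- function(values, labels, attributes,
                                  purity_threshold = 1, min_size = 1L,
                                  seed = NULL) {
  if (inherits(labels, "discretized_target")) labels <- labels$labels
  labels <- as.integer(labels)
  attributes <- as.integer(attributes)
  if (length(attributes) == 0L) stop("attribute subset B must be non-empty")
  if (purity_threshold <= 0 || purity_threshold > 1) {
    stop("purity_threshold must lie in (0, 1]")
  }
  X <- as.matrix(values)[, attributes, drop = FALSE]
  n <- nrow(X)
  stopifnot(length(labels) == n)
  pending <- list(new_ball(seq_len(n), X, labels))
  done <- list()
  while (length(pending) > 0L) {
    ball <- pending[[1L]]
    pending <- pending[-1L]
    needs_split <- ball$splittable &&
      ball$purity < purity_threshold &&
      length(ball$members) > min_size
    if (!needs_split) {
      done[[length(done) + 1L]] <- ball
      next
    }
    children <- gb_split_ball(ball, X, labels)
    if (length(children) == 1L) {
      done[[length(done) + 1L]] <- children[[1L]]
    } else {
      pending <- c(pending, children)
    }
  }
  part <- structure(
    list(balls = done, attribute_subset = attributes,
         purity_threshold = purity_threshold, n = n, coverage = NA_integer_),
    class = "gb_partition")
  part$coverage <- gb_coverage(part)
  part
}

#' Sample coverage of a granular-ball partition
#'
#' The number of samples lying in balls whose purity reaches the partition's
#' purity threshold. At threshold 1 this is the size of the positive region:
#' the union of equivalence classes wholly contained in one decision class.
#'
#' @param partition a `gb_partition`.
#' @param count_singletons if `FALSE`, pure balls with a single member do not
#'   count toward coverage. Singletons are trivially pure, so on small noisy
#'   tables literal counting can saturate coverage at `n` for any attribute
#'   subset; attribute reduction therefore disables singleton counting by
#'   default (see [gbrs_forward_select()]).
#' @return Integer count, at most `partition$n`.
#' @export
gb_coverage <- function(partition, count_singletons = TRUE) {
  stopifnot(inherits(partition, "gb_partition"))
  covered <- vapply(partition$balls, function(b) {
    ok <- b$purity >= partition$purity_threshold &&
      (count_singletons || length(b$members) >= 2L)
    if (ok) length(b$members) else 0L
  }, integer(1))
  as.integer(sum(covered))
}

#' @export
print.gb_partition <- function(x, ...) {
  sizes <- vapply(x$balls, function(b) length(b$members), integer(1))
  cat(sprintf(
    "gb_partition: %d ball(s) over %d samples (attributes %s, purity >= %g)\n",
    length(x$balls), x$n, paste(x$attribute_subset, collapse = ","),
    x$purity_threshold))
  cat(sprintf("ball sizes: %s; coverage %d/%d\n",
              paste(sizes, collapse = " "), x$coverage, x$n))
  invisible(x)
}

#' Dump a partition to JSON for inspection
#'
#' @param partition a `gb_partition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gb_partition <- function(partition, path) {
  stopifnot(inherits(partition, "gb_partition"))
  balls <- lapply(partition$balls, function(b) {
    list(center = unname(b$center), radius = b$radius,
         members = b$members, majority_label = b$majority_label,
         purity = b$purity)
  })
  jsonlite::write_json(
    list(attribute_subset = partition$attribute_subset,
         purity_threshold = partition$purity_threshold,
         n = partition$n, coverage = partition$coverage, balls = balls),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
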