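#' Rough-set approximations over a granular-ball partition
#'
#' With the balls of a partition playing the role of equivalence classes, the
#' lower approximation of a decision concept is the union of balls wholly
#' contained in the concept's sample set, and the upper approximation the
#' union of balls intersecting it.
#'
#' @param partition a `gb_partition` from [generate_gb_partition()].
#' @param labels integer class labels (or a `discretized_target`) used to
#'   build the partition.
#' @param concept the class code whose approximations are wanted.
#' @return An object of class `gb_approximation`: sorted index sets `lower`
#'   and `upper`, plus `concept` and `attribute_subset`. Always
#'   `lower` \eqn{\subseteq} `upper`.
#' @export
gb_approximate <- function(partition, labels, concept) {
  stopifnot(inherits(partition, "gb_partition"))
  if (inherits(labels, "discretized_target")) labels <- labels$labels
  labels <- as.integer(labels)
  concept <- as.integer(concept)
  if (!concept %in% labels) stop("unknown class code: ", concept)
  lower <- integer(0)
  upper <- integer(0)
  for (b in partition$balls) {
    in_concept <- labels[b$members] == concept
    if (any(in_concept)) upper <- c(upper, b$members)
    if (all(in_concept)) lower <- c(lower, b$members)
  }
  structure(list(lower = sort(lower), upper = sort(upper), concept = concept,
                 attribute_subset = partition$attribute_subset),
            class = "gb_approximation")
}

#' Size of the positive region under an attribute subset
#'
#' Generates the granular-ball partition induced by attribute subset `B` and
#' returns its coverage. At `purity_threshold = 1` (the default) this equals
#' the summed sizes of the per-class lower approximations: the number of
#' samples whose ball is unanimous about the decision class.
#'
#' @inheritParams generate_gb_partition
#' @param B integer attribute subset.
#' @param count_singletons passed to [gb_coverage()]; default `TRUE`
#'   (literal counting, preserving the lower-approximation identity).
#' @return Integer coverage count.
#' @export
positive_region_size <- function(values, labels, B, purity_threshold = 1,
                                 min_size = 1L, count_singletons = TRUE) {
  part <- generate_gb_partition(values, labels, B,
                                purity_threshold = purity_threshold,
                                min_size = min_size)
  gb_coverage(part, count_singletons = count_singletons)
}

#' Greedy forward attribute reduction by positive-region coverage
#'
#' The reduction loop of the granular-ball rough set method: starting from an
#' empty attribute set, each condition attribute is tried in turn; the
#' granular-ball partition is regenerated with the candidate attribute added,
#' and the attribute is retained exactly when the number of samples covered
#' by pure balls strictly increases. One pass is made over the attributes and
#' rejected attributes are not retried.
#'
#' Labels default to quantile bins of the decision attribute
#' ([discretize_target()]), and attribute values are min-max normalised
#' before any distance is computed; both are configurable.
#'
#' @param table a [sample_table()].
#' @param labels optional `discretized_target` or integer labels; defaults to
#'   `discretize_target(table, q)`.
#' @param order attribute ordering to try: `NULL` for column order (the
#'   default), the string `"pearson"` for descending absolute correlation
#'   with the target, or an explicit integer permutation.
#' @param q bin count for the default discretisation.
#' @param purity_threshold,min_size passed to [generate_gb_partition()].
#' @param count_singletons if `FALSE` (default) pure single-member balls do
#'   not count toward coverage during selection, guarding against spurious
#'   saturation; `TRUE` restores literal counting.
#' @param normalize min-max normalise attributes before computing distances
#'   (default `TRUE`).
#' @return An object of class `gbrs_reduct`: `selected` (retained attribute
#'   indices, in retention order), `coverage_trace` (one row per attribute
#'   tried: index, name, coverage before and after, retained flag),
#'   `final_coverage`, `n` and `q`.
#' @export
gbrs_forward_select <- function(table, labels = NULL, order = NULL, q = 3L,
                                purity_threshold = 1, min_size = 1L,
                                count_singletons = FALSE, normalize = TRUE) {
  stopifnot(inherits(table, "sample_table"))
  if (is.null(labels)) labels <- discretize_target(table, q)
  if (inherits(labels, "discretized_target")) labels <- labels$labels
  labels <- as.integer(labels)
  v <- if (normalize) min_max_normalize(table)$values else table$values
  d <- ncol(v)
  if (is.null(order)) {
    order <- seq_len(d)
  } else if (identical(order, "pearson")) {
    order <- rank_attributes(table)$order
  } else {
    order <- as.integer(order)
    stopifnot(all(order %in% seq_len(d)))
  }
  selected <- integer(0)
  cov <- 0L
  trace <- vector("list", length(order))
  for (i in seq_along(order)) {
    a <- order[i]
    cand <- c(selected, a)
    cov_new <- positive_region_size(v, labels, cand,
                                    purity_threshold = purity_threshold,
                                    min_size = min_size,
                                    count_singletons = count_singletons)
    retained <- cov_new > cov
    trace[[i]] <- data.frame(attribute = a,
                             name = table$attribute_names[a],
                             coverage_before = cov,
                             coverage_after = cov_new,
                             retained = retained)
    if (retained) {
      selected <- cand
      cov <- cov_new
    }
  }
  structure(list(selected = selected,
                 coverage_trace = do.call(rbind, trace),
                 final_coverage = cov,
                 n = nrow(v), q = length(unique(labels))),
            class = "gbrs_reduct")
}

#' @export
print.gbrs_reduct <- function(x, ...) {
  cat(sprintf("gbrs_reduct: %d attribute(s) retained, coverage %d/%d\n",
              length(x$selected), x$final_coverage, x$n))
  tr <- x$coverage_trace
  tr$retained <- ifelse(tr$retained, "yes", "no")
  print(tr, row.names = FALSE)
  invisible(x)
}

#' Serialise a reduct to JSON
#'
#' @param reduct a `gbrs_reduct`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reduct <- function(reduct, path) {
  stopifnot(inherits(reduct, "gbrs_reduct"))
  jsonlite::write_json(
    list(selected = reduct$selected,
         final_coverage = reduct$final_coverage,
         n = reduct$n,
         coverage_trace = reduct$coverage_trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
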