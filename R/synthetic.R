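#' Specification of a synthetic monitoring table
#'
#' Describes a synthetic hydrological/water-quality table with a planted
#' attribute structure: `d_informative` seasonally autocorrelated attributes
#' that drive the chlorophyll target, `d_redundant` jittered affine copies of
#' informative attributes, and `d_noise` pure-noise attributes. The default
#' preset mirrors a small river monitoring campaign: 68 samples (five years
#' of monthly records followed by eight sparser ones), 13 condition
#' attributes (3 informative + 4 redundant + 6 noise), and a non-negative,
#' right-skewed target on a heavy scale resembling per-phylum chlorophyll
#' quantities.
#'
#' @param n sample count (default 68; at least 4).
#' @param d_informative,d_redundant,d_noise attribute counts (defaults
#'   3, 4, 6). `d_redundant > 0` requires `d_informative > 0`.
#' @param effect shape of the map from informative attributes + season to
#'   the target: `"exponential"` (default; bloom-like spikes), `"linear"`,
#'   or `"threshold"`.
#' @param noise_sd standard deviation of the additive Gaussian target noise,
#'   as a fraction of `target_scale` (default 0.3).
#' @param target_scale multiplicative scale of the target (default 1000).
#' @param season_weight weight of the seasonal term inside the effect
#'   (default 0.5; set 0 for a purely attribute-driven target).
#' @param redundant_jitter relative standard deviation of the jitter added to
#'   redundant copies (default 0.1, keeping `|rho| > 0.9` with the source).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_monitoring_table()], [planted_truth()]
#' @export
synthetic_spec <- function(n = 68L, d_informative = 3L, d_redundant = 4L,
                           d_noise = 6L,
                           effect = c("exponential", "linear", "threshold"),
                           noise_sd = 0.3, target_scale = 1000,
                           season_weight = 0.5, redundant_jitter = 0.1,
                           seed = 1L) {
  effect <- match.arg(effect)
  n <- as.integer(n)
  d_informative <- as.integer(d_informative)
  d_redundant <- as.integer(d_redundant)
  d_noise <- as.integer(d_noise)
  d <- d_informative + d_redundant + d_noise
  if (n < 4L) stop("n must be at least 4")
  if (d < 1L) stop("at least one condition attribute is required")
  if (min(d_informative, d_redundant, d_noise) < 0L) {
    stop("attribute counts must be non-negative")
  }
  if (d_redundant > 0L && d_informative == 0L) {
    stop("redundant attributes need an informative source")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n = n, d_informative = d_informative,
                 d_redundant = d_redundant, d_noise = d_noise,
                 effect = effect, noise_sd = as.numeric(noise_sd),
                 target_scale = as.numeric(target_scale),
                 season_weight = as.numeric(season_weight),
                 redundant_jitter = as.numeric(redundant_jitter),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic monitoring table
#'
#' Draws a [sample_table()] according to a [synthetic_spec()]:
#' \itemize{
#'   \item a monthly time axis with a 12-sample seasonal sinusoid, switching
#'     to quarterly spacing after sample 60 (the cadence change typical of
#'     long monitoring campaigns);
#'   \item informative attributes = phase-shifted seasonal signal plus AR(1)
#'     noise;
#'   \item redundant attributes = affine copies of informative attributes
#'     plus small jitter;
#'   \item noise attributes = i.i.d. standard normal draws;
#'   \item target = `effect(informative, season) * target_scale` plus
#'     Gaussian noise, clipped at zero (chlorophyll quantities are
#'     non-negative and right-skewed).
#' }
#' Identical specs (including the seed) give bit-identical tables.
#'
#' @param spec a [synthetic_spec()].
#' @return A [sample_table()] whose target column is named `chlorophyll`.
#' @export
generate_monitoring_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n
  di <- spec$d_informative
  dr <- spec$d_redundant
  dn <- spec$d_noise
  with_seed(spec$seed, {
    # monthly cadence, then quarterly after sample 60
    t_months <- ifelse(seq_len(n) <= 60L, seq_len(n),
                       60L + 3L * (seq_len(n) - 60L))
    season <- sin(2 * pi * t_months / 12)
    inform <- matrix(0, n, di)
    if (di > 0L) {
      for (j in seq_len(di)) {
        phase <- (j - 1) * pi / 4
        ar <- as.numeric(stats::filter(stats::rnorm(n, 0, 0.5), 0.6,
                                       method = "recursive"))
        inform[, j] <- sin(2 * pi * t_months / 12 + phase) + ar
      }
    }
    redund <- matrix(0, n, dr)
    if (dr > 0L) {
      for (j in seq_len(dr)) {
        src <- ((j - 1L) %% di) + 1L
        s <- inform[, src]
        redund[, j] <- 0.5 + 1.5 * s +
          stats::rnorm(n, 0, spec$redundant_jitter * stats::sd(s))
      }
    }
    noise <- if (dn > 0L) matrix(stats::rnorm(n * dn), n, dn) else
      matrix(0, n, 0L)
    # standardised linear index over the informative attributes
    eta <- if (di > 0L) {
      w <- 1.5 * 0.75^(seq_len(di) - 1)
      drop(scale(inform) %*% w) / sqrt(sum(w^2))
    } else {
      rep(0, n)
    }
    idx <- eta + spec$season_weight * season
    g <- switch(spec$effect,
                exponential = exp(idx),
                linear = idx - min(idx),
                threshold = 0.25 + 1.5 * (idx > 0))
    target <- pmax(0, spec$target_scale * g +
                     stats::rnorm(n, 0, spec$noise_sd * spec$target_scale))
    values <- cbind(inform, redund, noise)
    colnames(values) <- c(
      if (di > 0L) paste0("inf", seq_len(di)),
      if (dr > 0L) paste0("red", seq_len(dr)),
      if (dn > 0L) paste0("rnd", seq_len(dn)))
    tab <- sample_table(values, target)
    attr(tab, "target_name") <- "chlorophyll"
    tab
  })
}

#' Planted attribute roles of a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return A list of integer index sets `informative`, `redundant` and
#'   `noise` (columns of the generated table), for scoring how well a
#'   selection procedure recovers the planted structure.
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  di <- spec$d_informative
  dr <- spec$d_redundant
  dn <- spec$d_noise
  list(informative = seq_len(di),
       redundant = if (dr > 0L) di + seq_len(dr) else integer(0),
       noise = if (dn > 0L) di + dr + seq_len(dn) else integer(0))
}

#' Selection recovery score
#'
#' Fraction of selected attributes that are relevant (informative or
#' redundant copies thereof): the size of the intersection of `selected`
#' with the union of the informative and redundant sets, divided by
#' `|selected|`.
#'
#' @param selected integer vector of selected attribute indices.
#' @param truth a [planted_truth()] list.
#' @return A fraction in `[0, 1]`; `NaN` for an empty selection.
#' @export
recovery_score <- function(selected, truth) {
  relevant <- c(truth$informative, truth$redundant)
  length(intersect(selected, relevant)) / length(selected)
}

#' Round-trip a synthetic spec through YAML
#'
#' @param spec a [synthetic_spec()].
#' @param path YAML file path.
#' @return `write_synthetic_spec()` returns `path` invisibly;
#'   `read_synthetic_spec()` the restored spec.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(synthetic_spec, obj)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: n=%d, attributes %d informative + %d redundant + %d noise\n",
    x$n, x$d_informative, x$d_redundant, x$d_noise))
  cat(sprintf("effect %s, noise_sd %g, target_scale %g, seed %d\n",
              x$effect, x$noise_sd, x$target_scale, x$seed))
  invisible(x)
}
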