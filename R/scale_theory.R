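# Concentration theory for FracMinHash sketch sizes and the derived
# accuracy guarantees. A sketch size X_A is a sum of |A| independent
# Bernoulli(s) indicators (one per element, under a strongly 2-universal
# hash family), so E[X_A] = s|A| and the classic Chernoff bound controls
# its relative deviation. Pushing three such bounds through the ratio
# defining the cosine (or Sorensen / Bray-Curtis / Kulczynski-1) yields
# the probability guarantees and, inverted, the recommended scale factor.

#' Expected FracMinHash sketch size
#'
#' @param s scale factor in `[0, 1]`.
#' @param n number of distinct elements in the source set.
#' @return `s * n` (vectorized).
#' @export
expected_sketch_size <- function(s, n) {
  stopifnot(all(s >= 0 & s <= 1), all(n >= 0))
  s * n
}

#' Chernoff tail bound on the sketch size
#'
#' Upper-bounds the probability that a sketch of an `n`-element set
#' deviates from its expectation by a relative factor `epsilon` or more:
#' `Pr[|X - s n| >= epsilon s n] <= 2 exp(-s n epsilon^2 / 3)`, clamped
#' at 1 (the bound is vacuous when `s n` is tiny).
#'
#' @param s scale factor in `[0, 1]`.
#' @param n source-set size.
#' @param epsilon relative deviation in `(0, 1)`.
#' @return The (clamped) probability bound, vectorized over the inputs.
#' @examples
#' sketch_size_tail_bound(0.05, 10000, 0.1)
#' @export
sketch_size_tail_bound <- function(s, n, epsilon) {
  stopifnot(all(s >= 0 & s <= 1), all(n >= 0))
  if (any(epsilon <= 0 | epsilon >= 1))
    stop("'epsilon' must lie strictly in (0, 1)")
  pmin(1, 2 * exp(-s * n * epsilon^2 / 3))
}

#' Probability guarantee for a sketch-based metric estimate
#'
#' Lower bound on the probability that the plug-in estimate falls within a
#' relative error `epsilon` of the true value. For cosine, Sorensen and
#' Bray-Curtis the bound is
#' `1 - 6 exp(-s |A n B| epsilon^2 / [3 (2+epsilon)^2])`; for the first
#' Kulczynski measure it is
#' `1 - 4 exp(-s min(|A n B|, |A delta B|) epsilon^2 / [3 (2+epsilon)^2])`.
#' Bounds are clamped below at 0; when `s |A n B|` is small the guarantee
#' is vacuous (highly dissimilar sets produce near-empty sketches and the
#' bound carries no information, even though a near-zero estimate still
#' reflects the dissimilarity).
#'
#' @param metric one of `"cosine"`, `"kulczynski1"`, `"sorensen"`,
#'   `"bray_curtis"` (the measures without a tractable unbiased estimator).
#' @param s scale factor.
#' @param size_intersection true `|A n B|`.
#' @param size_symmetric_difference true `|A delta B|`; required for
#'   `"kulczynski1"` only.
#' @param epsilon tolerable relative error in `(0, 1)`.
#' @return An object of class `fmh_bound` with field
#'   `probability_lower_bound` in `[0, 1]`.
#' @export
metric_error_bound <- function(metric = c("cosine", "kulczynski1", "sorensen",
                                          "bray_curtis"),
                               s, size_intersection,
                               size_symmetric_difference = NULL, epsilon) {
  metric <- match.arg(metric)
  stopifnot(length(s) == 1L, s >= 0, s <= 1,
            length(size_intersection) == 1L, size_intersection >= 0)
  if (length(epsilon) != 1L || epsilon <= 0 || epsilon >= 1)
    stop("'epsilon' must lie strictly in (0, 1)")
  if (metric == "kulczynski1") {
    if (is.null(size_symmetric_difference))
      stop("'size_symmetric_difference' is required for kulczynski1")
    stopifnot(size_symmetric_difference >= 0)
    m <- min(size_intersection, size_symmetric_difference)
    raw <- 1 - 4 * exp(-s * m * epsilon^2 / (3 * (2 + epsilon)^2))
  } else {
    raw <- 1 - 6 * exp(-s * size_intersection * epsilon^2 /
                         (3 * (2 + epsilon)^2))
  }
  structure(list(metric = metric, s = s,
                 size_intersection = size_intersection,
                 size_symmetric_difference = size_symmetric_difference,
                 epsilon = epsilon,
                 probability_lower_bound = min(1, max(0, raw))),
            class = "fmh_bound")
}

#' @export
print.fmh_bound <- function(x, ...) {
  cat(sprintf(
    "P[ |%s' - %s| <= %g %s ] >= %.6f  (s = %g, |A n B| = %g)\n",
    x$metric, x$metric, x$epsilon, x$metric, x$probability_lower_bound,
    x$s, x$size_intersection))
  invisible(x)
}

#' Recommended minimum scale factor
#'
#' Inverts the cosine probability guarantee: to have confidence at least
#' `alpha` that the sketch-based cosine falls within a relative error
#' `epsilon` of the truth, use
#' `s = 3 (2+epsilon)^2 ln[6/(1-alpha)] / (epsilon^2 * m)`,
#' capped at 1, where `m = min(|A|, |B|)`. Using the minimum set size
#' rather than `|A n B|` is the practical recommendation (the intersection
#' size is rarely known in advance, and for highly dissimilar sets a
#' near-zero estimate is informative anyway); pass `size_intersection` to
#' use the sharper `min(|A|, |B|, |A n B|)` form.
#'
#' @param min_size `min(|A|, |B|)`, a positive count.
#' @param epsilon tolerable relative error, strictly in `(0, 1)`.
#' @param alpha desired confidence level in `[0, 1)`.
#' @param size_intersection optional true `|A n B|` for the sharper bound.
#' @return The recommended scale factor, a value in `(0, 1]`.
#' @examples
#' recommend_scale_factor(100000, 0.05, 0.95)   # 0.2414
#' @export
recommend_scale_factor <- function(min_size, epsilon, alpha,
                                   size_intersection = NULL) {
  stopifnot(length(min_size) == 1L, min_size >= 1)
  if (length(epsilon) != 1L || epsilon <= 0 || epsilon >= 1)
    stop("'epsilon' must lie strictly in (0, 1)")
  if (length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("'alpha' must lie in [0, 1); alpha = 1 would require an infinite sketch")
  m <- if (is.null(size_intersection)) min_size
       else min(min_size, size_intersection)
  min(1, 3 * (2 + epsilon)^2 * log(6 / (1 - alpha)) / (epsilon^2 * m))
}

# half-up rounding to `digits` decimals, the convention used when
# rendering scale-factor tables
round_half_up <- function(x, digits = 4) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Scale-factor lookup table
#'
#' Tabulates [recommend_scale_factor()] over grids of tolerable error and
#' confidence, rendered half-up to four decimals (a cell of 1.0000 means
#' no sub-sampling is admissible at that resolution).
#'
#' @param min_size `min(|A|, |B|)`.
#' @param epsilons vector of tolerable relative errors.
#' @param alphas vector of confidence levels.
#' @return A numeric matrix (rows: epsilons, columns: alphas) of class
#'   `fmh_scale_table`; the unrounded values are kept in attribute `"raw"`.
#' @examples
#' scale_factor_table(1e7, epsilons = c(0.01, 0.05, 0.1),
#'                    alphas = c(0.91, 0.95, 0.99))
#' @export
scale_factor_table <- function(min_size, epsilons, alphas) {
  raw <- outer(epsilons, alphas,
               Vectorize(function(e, a) recommend_scale_factor(min_size, e, a)))
  out <- round_half_up(raw, 4)
  dimnames(out) <- dimnames(raw) <- list(epsilon = format(epsilons),
                                         alpha = format(alphas))
  structure(out, raw = raw, min_size = min_size, class = "fmh_scale_table")
}

#' @export
print.fmh_scale_table <- function(x, ...) {
  cat(sprintf("Recommended scale factors, min(|A|, |B|) = %g\n",
              attr(x, "min_size")))
  m <- matrix(sprintf("%.4f", x), nrow = nrow(x), dimnames = dimnames(x))
  print(m, quote = FALSE)
  invisible(x)
}
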