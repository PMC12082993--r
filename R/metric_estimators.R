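FMH_METRICS <- c("jaccard", "containment_AB", "containment_BA", "cosine",
                 "kulczynski1", "kulczynski2", "whittaker", "sorensen",
                 "bray_curtis")

FMH_CORRECTABLE <- c("jaccard", "containment_AB", "containment_BA",
                     "kulczynski2", "whittaker")

new_metric_estimate <- function(metric, value, corrected, inputs_note) {
  structure(list(metric = metric, value = value, corrected = corrected,
                 inputs_note = inputs_note),
            class = "fmh_metric_estimate")
}

#' @export
print.fmh_metric_estimate <- function(x, ...) {
  cat(sprintf("%s = %s%s\n", x$metric, format(x$value),
              if (x$corrected) " (bias-corrected)" else ""))
  n <- x$inputs_note
  cat(sprintf("  sizes used: |A| term = %g, |B| term = %g, intersection = %g\n",
              n$size_a, n$size_b, n$size_ab))
  invisible(x)
}

#' @export
as.double.fmh_metric_estimate <- function(x, ...) x$value

# Single formula path shared by the exact (set) and plug-in (sketch)
# computations. All nine measures are ratios of |A|, |B|, |A n B|,
# |A u B| and |A delta B|. `strict` controls the zero-denominator policy:
# exact set computation errors (the quantity truly is undefined), the
# sketch path degrades gracefully -- similarities report 0 (an empty sketch
# of a denominator set reflects extreme dissimilarity or undersampling) and
# their complement distances report 1, each with a warning.
metric_from_counts <- function(metric, n_a, n_b, n_ab,
                               strict = FALSE, warn = TRUE) {
  metric <- match.arg(metric, FMH_METRICS)
  n_a <- as.numeric(n_a); n_b <- as.numeric(n_b); n_ab <- as.numeric(n_ab)
  n_union <- n_a + n_b - n_ab
  n_symdiff <- n_union - n_ab
  degenerate <- function(value_if_lenient, what) {
    if (strict)
      stop(metric, " is undefined: ", what, " is empty")
    if (warn)
      warning("degenerate input for ", metric, ": ", what,
              " is empty; reporting limiting value ", value_if_lenient)
    value_if_lenient
  }
  switch(metric,
    jaccard = if (n_union == 0) degenerate(0, "A union B") else n_ab / n_union,
    containment_AB = if (n_a == 0) degenerate(0, "A") else n_ab / n_a,
    containment_BA = if (n_b == 0) degenerate(0, "B") else n_ab / n_b,
    cosine = if (n_a == 0 || n_b == 0) degenerate(0, "A or B")
             else n_ab / sqrt(n_a * n_b),
    kulczynski1 = if (n_symdiff == 0) {
        if (n_ab == 0) degenerate(0, "A union B") else Inf
      } else n_ab / n_symdiff,
    kulczynski2 = if (n_a == 0 || n_b == 0) degenerate(0, "A or B")
                  else 0.5 * (n_ab / n_a + n_ab / n_b),
    whittaker = if (n_a == 0 || n_b == 0) degenerate(1, "A or B")
                else 1 - 0.5 * (n_ab / n_a + n_ab / n_b),
    sorensen = if (n_a + n_b == 0) degenerate(0, "A and B")
               else 2 * n_ab / (n_a + n_b),
    bray_curtis = if (n_a + n_b == 0) degenerate(1, "A and B")
                  else 1 - 2 * n_ab / (n_a + n_b))
}

#' Exact similarity/dissimilarity between two finite sets
#'
#' Evaluates the measure on the sets themselves (no sketching); this is the
#' ground truth against which the sketch-based estimators are judged.
#' Available measures, on sets `A`, `B` with intersection `I`:
#' Jaccard `|I|/|A u B|`; containment `|I|/|A|` (or `|I|/|B|`); cosine
#' (Otsuka-Ochiai) `|I|/sqrt(|A| |B|)`; first Kulczynski `|I|/|A delta B|`;
#' second Kulczynski, the mean of the two containments; Whittaker distance
#' `1 - K2`; Sorensen `2|I|/(|A|+|B|)`; Bray-Curtis `1 - Sorensen`.
#'
#' @param a,b finite sets given as atomic vectors (duplicates are ignored).
#' @param metric one of `r paste0('"', FMH_METRICS, '"', collapse = ", ")`.
#' @return An `fmh_metric_estimate` (`$value` holds the number). An empty
#'   operand whose size appears in a denominator is an error; the first
#'   Kulczynski measure of two identical sets is reported as `Inf`.
#' @examples
#' metric_on_sets(1:6, 4:9, "cosine")$value    # 3 / sqrt(36) = 0.5
#' metric_on_sets(1:6, 4:9, "jaccard")$value   # 3 / 9
#' @export
metric_on_sets <- function(a, b, metric = FMH_METRICS) {
  metric <- match.arg(metric)
  a <- unique(a); b <- unique(b)
  n_ab <- length(intersect(a, b))
  value <- metric_from_counts(metric, length(a), length(b), n_ab,
                              strict = TRUE)
  new_metric_estimate(metric, value, corrected = FALSE,
                      inputs_note = list(size_a = length(a),
                                         size_b = length(b),
                                         size_ab = n_ab,
                                         size_union = length(a) + length(b) - n_ab,
                                         exact = TRUE))
}

#' Plug-in metric estimate from two sketches
#'
#' Evaluates the set formula with the sketch cardinalities `X_A`, `X_B`,
#' `X_{A n B}` in place of the true sizes. The plug-in estimate is exact at
#' `s = 1` and concentrates around the true value as `s |A n B|` grows; it
#' is biased for Jaccard/containment-type measures (see
#' [corrected_estimate()]).
#'
#' @param a,b compatible `fmh_sketch` objects.
#' @inheritParams metric_on_sets
#' @return An `fmh_metric_estimate` with `corrected = FALSE`. An empty
#'   sketch in a denominator position yields the limiting value (0 for
#'   similarities, 1 for Whittaker/Bray-Curtis) with a warning.
#' @export
plug_in_metric <- function(a, b, metric = FMH_METRICS) {
  metric <- match.arg(metric)
  check_compatible(a, b)
  x_a <- length(a$hashes); x_b <- length(b$hashes)
  x_ab <- cpp_u64str_intersection_size(a$hashes, b$hashes)
  value <- metric_from_counts(metric, x_a, x_b, x_ab, strict = FALSE)
  new_metric_estimate(metric, value, corrected = FALSE,
                      inputs_note = list(size_a = x_a, size_b = x_b,
                                         size_ab = x_ab,
                                         size_union = x_a + x_b - x_ab,
                                         scale_factor = a$params$scale_factor))
}

# count-level corrected estimators (shared with the simulation harness):
# multiply the plug-in value by 1 / (1 - (1-s)^n) where n is the
# denominator set's true cardinality -- 1 - (1-s)^n is the probability that
# the denominator sketch is non-empty, which is exactly the factor by which
# the plug-in estimator (with 0/0 := 0) underestimates.
corrected_from_counts <- function(metric, x_a, x_b, x_ab, s,
                                  card_a, card_b, card_union) {
  stopifnot(s > 0)
  corr <- function(n) 1 / (1 - (1 - s)^n)
  plug <- function(m) metric_from_counts(m, x_a, x_b, x_ab,
                                         strict = FALSE, warn = FALSE)
  switch(metric,
    jaccard = plug("jaccard") * corr(card_union),
    containment_AB = plug("containment_AB") * corr(card_a),
    containment_BA = plug("containment_BA") * corr(card_b),
    kulczynski2 = 0.5 * (plug("containment_AB") * corr(card_a) +
                         plug("containment_BA") * corr(card_b)),
    whittaker = 1 - 0.5 * (plug("containment_AB") * corr(card_a) +
                           plug("containment_BA") * corr(card_b)),
    stop("no bias-corrected estimator exists for '", metric, "'"))
}

#' Bias-corrected metric estimate from two sketches
#'
#' The plug-in Jaccard and containment estimators are biased low by the
#' probability that the denominator sketch is empty: their expectation is
#' the true value times `1 - (1-s)^n`, with `n` the denominator set's true
#' cardinality. Dividing by that factor gives an unbiased estimator.
#' Corrections exist for Jaccard (`n = |A u B|`), the containments
#' (`n = |A|` or `|B|`), the second Kulczynski index (mean of the two
#' corrected containments) and the Whittaker distance (`1 - K2hat`). No
#' tractable correction exists for cosine, Kulczynski-1, Sorensen or
#' Bray-Curtis; those are covered by probability bounds instead
#' (see [metric_error_bound()]).
#'
#' @param a,b compatible `fmh_sketch` objects with `scale_factor > 0`.
#' @param metric one of `r paste0('"', FMH_CORRECTABLE, '"', collapse = ", ")`.
#' @param cardinality_a,cardinality_b,cardinality_union exact cardinalities
#'   of `A`, `B` and `A u B` when known. Defaults: the sketch's stored
#'   `source_cardinality` if present, else the sketch-based estimate
#'   `X / s` (a notice is emitted, since the correction is then itself
#'   estimated).
#' @return An `fmh_metric_estimate` with `corrected = TRUE`.
#' @export
corrected_estimate <- function(a, b, metric = FMH_CORRECTABLE,
                               cardinality_a = NULL, cardinality_b = NULL,
                               cardinality_union = NULL) {
  metric <- match.arg(metric)
  check_compatible(a, b)
  s <- a$params$scale_factor
  if (s <= 0)
    stop("bias correction undefined at scale factor 0")
  x_a <- length(a$hashes); x_b <- length(b$hashes)
  x_ab <- cpp_u64str_intersection_size(a$hashes, b$hashes)
  card_of <- function(given, sk, label) {
    if (!is.null(given)) return(as.numeric(given))
    if (!is.null(sk$source_cardinality)) return(sk$source_cardinality)
    message("exact |", label, "| unavailable; using sketch estimate ",
            "X/s for the correction factor")
    length(sk$hashes) / s
  }
  card_a <- if (metric %in% c("containment_AB", "kulczynski2", "whittaker"))
    card_of(cardinality_a, a, "A") else NA_real_
  card_b <- if (metric %in% c("containment_BA", "kulczynski2", "whittaker"))
    card_of(cardinality_b, b, "B") else NA_real_
  card_union <- if (metric == "jaccard") {
    if (!is.null(cardinality_union)) as.numeric(cardinality_union)
    else {
      message("exact |A u B| unavailable; using sketch estimate ",
              "X_union/s for the Jaccard correction factor")
      (x_a + x_b - x_ab) / s
    }
  } else NA_real_
  value <- corrected_from_counts(metric, x_a, x_b, x_ab, s,
                                 card_a, card_b, card_union)
  new_metric_estimate(metric, value, corrected = TRUE,
                      inputs_note = list(size_a = x_a, size_b = x_b,
                                         size_ab = x_ab,
                                         size_union = x_a + x_b - x_ab,
                                         card_a = card_a, card_b = card_b,
                                         card_union = card_union,
                                         scale_factor = s))
}
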