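# Simulation harness: random set pairs from an integer universe, sketch
# them, estimate the cosine, and tabulate how often the estimate falls
# within a relative tolerance of the truth. Doubles as the Monte-Carlo
# oracle for the unbiasedness and concentration properties.
#
# Two element modes:
#   "hashed" -- universe elements are hashed for real (8-byte little-endian
#     encoding through MurmurHash3, same acceptance threshold as k-mer
#     sketches), exercising the full stack including hash quality;
#   "ideal"  -- each element receives an i.i.d. uniform draw on [0, 1] and
#     is retained iff it is <= s, i.e. sketching under an idealized
#     strongly-universal hash family. Useful for isolating estimator
#     behavior from hash quality, and cheaper on very large sets.

#' Simulation configuration
#'
#' @param universe_size number of elements in the universe (default 1e6).
#' @param set_sizes a list of `c(|A|, |B|)` pairs, or a 2-column matrix;
#'   defaults to the full 5x5 grid of 100K..500K.
#' @param scale_mode `"fixed"` (use `fixed_s` everywhere) or
#'   `"recommended"` (per-cell [recommend_scale_factor()] from
#'   `min(|A|, |B|)`, `epsilon`, `alpha`).
#' @param fixed_s scale factor used in fixed mode (default 0.001, the
#'   sourmash default).
#' @param epsilon relative tolerance of the within-window check (and of
#'   the recommendation in `"recommended"` mode).
#' @param alpha confidence level for the recommendation.
#' @param repetitions independent trials per cell (default 1000).
#' @param seed integer RNG seed; each grid cell derives its own substream
#'   so cells are reproducible independently of one another.
#' @param element_mode `"hashed"` or `"ideal"` (see Details).
#' @param hash_seed MurmurHash3 seed used in hashed mode.
#' @return An object of class `fmh_sim_config`.
#' @export
simulation_config <- function(universe_size = 1e6,
                              set_sizes = NULL,
                              scale_mode = c("fixed", "recommended"),
                              fixed_s = 0.001,
                              epsilon = 0.05,
                              alpha = 0.95,
                              repetitions = 1000,
                              seed = 1L,
                              element_mode = c("hashed", "ideal"),
                              hash_seed = 42L) {
  scale_mode <- match.arg(scale_mode)
  element_mode <- match.arg(element_mode)
  if (is.null(set_sizes)) {
    grid <- as.matrix(expand.grid(a = seq(1e5, 5e5, by = 1e5),
                                  b = seq(1e5, 5e5, by = 1e5)))
  } else if (is.matrix(set_sizes)) {
    grid <- set_sizes
  } else {
    grid <- do.call(rbind, set_sizes)
  }
  storage.mode(grid) <- "double"
  colnames(grid) <- c("size_a", "size_b")
  if (any(grid > universe_size))
    stop("set sizes cannot exceed the universe size")
  stopifnot(repetitions >= 1, universe_size >= 1,
            fixed_s >= 0, fixed_s <= 1,
            epsilon > 0, epsilon < 1, alpha >= 0, alpha < 1)
  structure(list(universe_size = universe_size, set_sizes = grid,
                 scale_mode = scale_mode, fixed_s = fixed_s,
                 epsilon = epsilon, alpha = alpha,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), element_mode = element_mode,
                 hash_seed = as.integer(hash_seed)),
            class = "fmh_sim_config")
}

#' @export
print.fmh_sim_config <- function(x, ...) {
  cat(sprintf(
    "Coverage simulation: universe %g, %d cell(s), %d reps, %s scale (%s)\n",
    x$universe_size, nrow(x$set_sizes), x$repetitions,
    x$scale_mode,
    if (x$scale_mode == "fixed") sprintf("s = %g", x$fixed_s)
    else sprintf("epsilon = %g, alpha = %g", x$epsilon, x$alpha)))
  cat(sprintf("  element mode: %s, seed %d\n", x$element_mode, x$seed))
  invisible(x)
}

#' Draw a random pair of sets from an integer universe
#'
#' `A` and `B` are independent uniform subsets (without replacement within
#' each set) of `{1, ..., universe_size}`, so `|A n B|` is hypergeometric
#' with mean `|A| |B| / N`. Uses the current RNG state.
#'
#' @param universe_size universe cardinality `N`.
#' @param n_a,n_b set sizes (each at most `N`).
#' @return A list with integer vectors `a` and `b`.
#' @export
sample_set_pair <- function(universe_size, n_a, n_b) {
  if (n_a > universe_size || n_b > universe_size)
    stop("set size exceeds universe size")
  list(a = sample.int(universe_size, n_a),
       b = sample.int(universe_size, n_b))
}

# per-trial sketch cardinalities (X_A, X_B, X_{A n B}) without
# materializing sketch objects; consistency (shared elements share their
# acceptance draw) is automatic in hashed mode and enforced in ideal mode
# by drawing once per element of A and reusing those draws for A n B.
trial_counts <- function(a, b, s, element_mode, hash_seed, universe_size) {
  in_b <- logical(universe_size)
  in_b[b] <- TRUE
  mask_ab <- in_b[a]                  # positions in a of intersection elements
  n_ab <- sum(mask_ab)
  if (element_mode == "hashed") {
    memb_a <- cpp_ints_in_sketch(a, hash_seed, s)
    memb_b <- cpp_ints_in_sketch(b, hash_seed, s)
    x_a <- sum(memb_a)
    x_b <- sum(memb_b)
    x_ab <- sum(memb_a[mask_ab])
  } else {
    u_a <- runif(length(a))
    x_a <- sum(u_a <= s)
    x_ab <- sum(u_a[mask_ab] <= s)
    x_b <- x_ab + sum(runif(length(b) - n_ab) <= s)
  }
  list(x_a = x_a, x_b = x_b, x_ab = x_ab, n_ab = n_ab)
}

#' Run one cosine estimation trial
#'
#' Computes the true cosine of `a` and `b` from all elements, the plug-in
#' cosine from FracMinHash sketches at scale `s`, and whether the estimate
#' falls within `epsilon` relative error of the truth. When the sampled
#' intersection is empty the true cosine is 0 and the trial counts as
#' within tolerance iff the estimate is exactly 0.
#'
#' @param a,b integer vectors (distinct elements of the universe).
#' @param s scale factor.
#' @param epsilon relative tolerance.
#' @param element_mode `"hashed"` or `"ideal"`.
#' @param hash_seed MurmurHash3 seed for hashed mode.
#' @param universe_size universe cardinality (only used to size an internal
#'   membership table; defaults to `max(a, b)`).
#' @return A list with `true_cos`, `est_cos` and logical `within`.
#' @export
run_cosine_trial <- function(a, b, s, epsilon = 0.05,
                             element_mode = c("hashed", "ideal"),
                             hash_seed = 42L, universe_size = NULL) {
  element_mode <- match.arg(element_mode)
  if (is.null(universe_size)) universe_size <- max(a, b)
  ct <- trial_counts(a, b, s, element_mode, hash_seed, universe_size)
  true_cos <- metric_from_counts("cosine", length(a), length(b), ct$n_ab,
                                 strict = TRUE)
  est_cos <- metric_from_counts("cosine", ct$x_a, ct$x_b, ct$x_ab,
                                strict = FALSE, warn = FALSE)
  within <- if (true_cos == 0) est_cos == 0
            else abs(est_cos - true_cos) <= epsilon * true_cos
  list(true_cos = true_cos, est_cos = est_cos, within = within)
}

# deterministic per-cell substream seed, kept within the 32-bit range
cell_seed <- function(seed, cell_index) {
  as.integer((as.numeric(seed) * 48271 + cell_index * 16807) %%
               .Machine$integer.max)
}

#' Coverage experiment over a grid of set-size pairs
#'
#' For every `(|A|, |B|)` cell, repeatedly samples random set pairs from
#' the universe, estimates the cosine from sketches, and reports the
#' fraction of trials whose estimate lands within `epsilon` relative error
#' of the true cosine. In `"recommended"` scale mode the per-cell scale
#' factor is recomputed from `min(|A|, |B|)` with the configured
#' `(epsilon, alpha)`, in which case the expected coverage is at least
#' `alpha` in every cell.
#'
#' @param config an [simulation_config()] object.
#' @return A data frame of class `fmh_coverage` with one row per cell:
#'   `size_a`, `size_b`, `s_used`, `fraction_within`, `n_zero_intersection`
#'   (trials whose sampled intersection was empty), and `repetitions`.
#'   Identical configurations (including `seed`) replay identically.
#' @export
coverage_experiment <- function(config) {
  stopifnot(inherits(config, "fmh_sim_config"))
  grid <- config$set_sizes
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    n_a <- grid[i, 1]; n_b <- grid[i, 2]
    s <- if (config$scale_mode == "fixed") config$fixed_s
         else recommend_scale_factor(min(n_a, n_b), config$epsilon,
                                     config$alpha)
    set.seed(cell_seed(config$seed, i))
    within <- logical(config$repetitions)
    n_zero <- 0L
    for (r in seq_len(config$repetitions)) {
      pair <- sample_set_pair(config$universe_size, n_a, n_b)
      tr <- run_cosine_trial(pair$a, pair$b, s, config$epsilon,
                             config$element_mode, config$hash_seed,
                             config$universe_size)
      within[r] <- tr$within
      if (tr$true_cos == 0) n_zero <- n_zero + 1L
    }
    rows[[i]] <- data.frame(size_a = n_a, size_b = n_b, s_used = s,
                            fraction_within = mean(within),
                            n_zero_intersection = n_zero,
                            repetitions = config$repetitions)
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("fmh_coverage", "data.frame")
  out
}

#' @export
print.fmh_coverage <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Fraction of %d trials with |est - true| <= %g * true cosine:\n",
              cfg$repetitions, cfg$epsilon))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Monte-Carlo check of estimator unbiasedness
#'
#' Builds a pair of sets with an exactly known overlap, repeatedly sketches
#' them, and compares the Monte-Carlo mean of the (corrected or plug-in)
#' estimator against the exact set value. The corrected estimators use the
#' exact cardinalities, as the correction assumes.
#'
#' @param metric one of the correctable measures
#'   (`r paste0('"', FMH_CORRECTABLE, '"', collapse = ", ")`).
#' @param n_a,n_b,n_intersection set sizes and their exact overlap.
#' @param s scale factor.
#' @param repetitions Monte-Carlo repetitions.
#' @param seed RNG seed.
#' @param element_mode `"hashed"` or `"ideal"`.
#' @param hash_seed MurmurHash3 seed (hashed mode). Note the sets are fixed
#'   in hashed mode, so sampling variation must come from varying
#'   `hash_seed` across repetitions; this is done automatically
#'   (`hash_seed + rep - 1`).
#' @param corrected apply the bias correction (`FALSE` gives the plug-in
#'   estimator, whose downward bias factor is `1 - (1-s)^n`).
#' @return A list of class `fmh_unbiasedness`: `true_value`, `mc_mean`,
#'   `mc_se`, `repetitions`, `metric`, `corrected`.
#' @export
unbiasedness_experiment <- function(metric = FMH_CORRECTABLE,
                                    n_a, n_b, n_intersection, s,
                                    repetitions = 2000, seed = 1L,
                                    element_mode = c("ideal", "hashed"),
                                    hash_seed = 42L, corrected = TRUE) {
  metric <- match.arg(metric)
  element_mode <- match.arg(element_mode)
  stopifnot(n_intersection <= min(n_a, n_b), s > 0, s <= 1)
  # fixed sets with exact overlap: A = 1..n_a, B = (n_a-n_I+1)..(n_a-n_I+n_b)
  a <- seq_len(n_a)
  b <- seq.int(n_a - n_intersection + 1, n_a - n_intersection + n_b)
  universe <- n_a - n_intersection + n_b
  n_union <- universe
  true_value <- metric_from_counts(metric, n_a, n_b, n_intersection,
                                   strict = TRUE)
  set.seed(seed)
  est <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    ct <- trial_counts(a, b, s, element_mode,
                       hash_seed = hash_seed + r - 1L,
                       universe_size = universe)
    est[r] <- if (corrected)
      corrected_from_counts(metric, ct$x_a, ct$x_b, ct$x_ab, s,
                            card_a = n_a, card_b = n_b,
                            card_union = n_union)
    else
      metric_from_counts(metric, ct$x_a, ct$x_b, ct$x_ab,
                         strict = FALSE, warn = FALSE)
  }
  structure(list(true_value = true_value, mc_mean = mean(est),
                 mc_se = stats::sd(est) / sqrt(repetitions),
                 repetitions = repetitions, metric = metric,
                 corrected = corrected, s = s),
            class = "fmh_unbiasedness")
}

#' @export
print.fmh_unbiasedness <- function(x, ...) {
  cat(sprintf("%s estimator (%s), s = %g, %d reps:\n", x$metric,
              if (x$corrected) "bias-corrected" else "plug-in",
              x$s, x$repetitions))
  cat(sprintf("  true = %.6f, MC mean = %.6f (SE %.2g), z = %.2f\n",
              x$true_value, x$mc_mean, x$mc_se,
              (x$mc_mean - x$true_value) / x$mc_se))
  invisible(x)
}

#' Monte-Carlo sample of sketch sizes
#'
#' Draws `repetitions` independent sketch sizes for an `n`-element set at
#' scale `s`, for verifying the Chernoff concentration bound empirically.
#'
#' @param n set size.
#' @param s scale factor.
#' @param repetitions number of independent sketches.
#' @param element_mode `"hashed"` (each repetition hashes the elements with
#'   a different seed) or `"ideal"` (i.i.d. uniform acceptance draws).
#' @param hash_seed base MurmurHash3 seed for hashed mode.
#' @return Integer vector of sketch sizes.
#' @export
sample_sketch_sizes <- function(n, s, repetitions,
                                element_mode = c("ideal", "hashed"),
                                hash_seed = 42L) {
  element_mode <- match.arg(element_mode)
  if (element_mode == "hashed") {
    elements <- seq_len(n)
    vapply(seq_len(repetitions),
           function(r) sum(cpp_ints_in_sketch(elements, hash_seed + r - 1L, s)),
           numeric(1))
  } else {
    # sum of n Bernoulli(s) indicators per repetition, drawn in blocks
    out <- numeric(repetitions)
    block <- max(1L, floor(5e6 / n))
    done <- 0L
    while (done < repetitions) {
      m <- min(block, repetitions - done)
      u <- matrix(runif(n * m) <= s, nrow = n)
      out[done + seq_len(m)] <- colSums(u)
      done <- done + m
    }
    out
  }
}
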