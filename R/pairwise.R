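#' Pairwise similarity/dissimilarity matrix from sketches
#'
#' Evaluates the chosen measure for every pair of sketches. Symmetric
#' measures are computed once per unordered pair; the (asymmetric)
#' containment is evaluated for ordered pairs, with cell `[i, j]` holding
#' `C(sample_i, sample_j)`. Diagonal cells are 1 for similarities and 0
#' for Whittaker/Bray-Curtis. A Kulczynski-1 value for identical sketches
#' is `Inf` (serialized as `"inf"` in CSV output).
#'
#' @param sketches a list of `fmh_sketch` objects sharing identical
#'   parameters; labels are taken from list names, falling back to each
#'   sketch's `name`.
#' @param metric one of `r paste0('"', FMH_METRICS, '"', collapse = ", ")`.
#' @param corrected apply the bias correction where one exists; defaults to
#'   `TRUE` for Jaccard/containment/Kulczynski-2/Whittaker and `FALSE`
#'   (plug-in) otherwise.
#' @return An object of class `fmh_pairwise`: `labels`, `metric`,
#'   `corrected`, `params`, and the numeric matrix `values`.
#' @export
compute_pairwise_matrix <- function(sketches, metric = "cosine",
                                    corrected = NULL) {
  metric <- match.arg(metric, FMH_METRICS)
  if (!is.list(sketches) || length(sketches) < 2L)
    stop("'sketches' must be a list of at least two sketches")
  labels <- names(sketches)
  if (is.null(labels))
    labels <- vapply(sketches, function(s) s$name, character(1))
  labels[!nzchar(labels)] <-
    paste0("sample", seq_along(sketches))[!nzchar(labels)]
  for (i in seq_along(sketches)) {
    ok <- tryCatch({ check_compatible(sketches[[1]], sketches[[i]]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop("sketches '", labels[1], "' and '", labels[i], "': ", ok)
  }
  if (is.null(corrected)) corrected <- metric %in% FMH_CORRECTABLE
  if (corrected && !metric %in% FMH_CORRECTABLE)
    stop("no bias-corrected estimator exists for '", metric, "'")

  n <- length(sketches)
  values <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(values) <- if (metric %in% c("whittaker", "bray_curtis")) 0
                  else if (metric == "kulczynski1") Inf  # |A delta A| = 0
                  else 1
  estimate_one <- function(i, j) {
    if (corrected)
      corrected_estimate(sketches[[i]], sketches[[j]], metric)$value
    else
      plug_in_metric(sketches[[i]], sketches[[j]], metric)$value
  }
  asymmetric <- metric %in% c("containment_AB", "containment_BA")
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      values[i, j] <- estimate_one(i, j)
      values[j, i] <- if (asymmetric) estimate_one(j, i) else values[i, j]
    }
  }
  structure(list(labels = labels, metric = metric, corrected = corrected,
                 params = sketches[[1]]$params, values = values),
            class = "fmh_pairwise")
}

#' @export
print.fmh_pairwise <- function(x, ...) {
  cat(sprintf("Pairwise %s matrix (%s), %d samples, k = %d, s = %g\n",
              x$metric, if (x$corrected) "bias-corrected" else "plug-in",
              length(x$labels), x$params$k, x$params$scale_factor))
  print(round(x$values, 4))
  invisible(x)
}

#' Write a pairwise matrix as CSV
#'
#' Full square matrix with labels in the first row and column, values at 6
#' decimal places, infinities written as the literal `inf`. A leading `#`
#' comment line records the metric, estimator type and sketch parameters.
#'
#' @param pm an `fmh_pairwise` object.
#' @param path output path (or `""` for standard output).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(pm, path) {
  stopifnot(inherits(pm, "fmh_pairwise"))
  fmt <- function(v) ifelse(is.infinite(v), "inf", sprintf("%.6f", v))
  lines <- c(
    sprintf("# fracminhash pairwise metric=%s estimator=%s k=%d scale_factor=%g hash_seed=%d",
            pm$metric, if (pm$corrected) "corrected" else "plug-in",
            pm$params$k, pm$params$scale_factor, pm$params$hash_seed),
    paste(c("", pm$labels), collapse = ","),
    vapply(seq_along(pm$labels),
           function(i) paste(c(pm$labels[i], fmt(pm$values[i, ])),
                             collapse = ","),
           character(1)))
  writeLines(lines, if (nzchar(path)) path else stdout())
  invisible(path)
}
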