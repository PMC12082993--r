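new_sketch <- function(hashes, params, name = "", source_cardinality = NULL) {
  structure(
    list(hashes = hashes, params = params, name = name,
         source_cardinality = if (is.null(source_cardinality) ||
                                  is.na(source_cardinality)) NULL
                              else as.numeric(source_cardinality)),
    class = "fmh_sketch")
}

#' Build a FracMinHash sketch from k-mers
#'
#' Hashes every distinct canonical k-mer and retains the hash values at or
#' below `floor(s * 2^64)`. At `s = 0` the sketch is empty; at `s = 1` it
#' holds the hash of every distinct k-mer.
#'
#' @param kmers character vector of k-mers (canonicalized internally).
#' @param params an [sketch_params()] object.
#' @param track_cardinality when `TRUE`, the exact number of distinct
#'   canonical k-mers in the input is stored on the sketch; the
#'   bias-corrected estimators ([corrected_estimate()]) use it in place of
#'   the sketch-based cardinality estimate.
#' @param name free-text sample label.
#' @return An object of class `fmh_sketch` with fields `hashes` (sorted,
#'   strictly increasing, decimal-encoded 64-bit values), `params`, `name`
#'   and optionally `source_cardinality`.
#' @examples
#' p <- sketch_params(k = 4, scale_factor = 1)
#' build_sketch(c("ACGT", "AAAA", "TTTT"), p)  # TTTT collapses onto AAAA
#' @export
build_sketch <- function(kmers, params, track_cardinality = FALSE, name = "") {
  stopifnot(inherits(params, "fmh_params"))
  if (!is.character(kmers)) stop("'kmers' must be a character vector")
  if (length(kmers) && any(nchar(kmers) != params$k))
    stop("all k-mers must have length k = ", params$k)
  res <- cpp_sketch_kmers(kmers, params$hash_seed, params$scale_factor,
                          TRUE, track_cardinality)
  new_sketch(res$hashes, params, name = name,
             source_cardinality = if (track_cardinality) res$n_distinct)
}

#' Sketch a FASTA or FASTQ file
#'
#' Builds one sketch over the union of canonical k-mers from all records in
#' the file. The format is auto-detected from the first non-blank character
#' (`>` FASTA, `@` FASTQ); gzip compression is handled transparently.
#' Quality scores are ignored, so a FASTQ file and a FASTA file holding the
#' same sequences produce identical sketches.
#'
#' @param path path to a FASTA/FASTQ file, optionally gzip-compressed.
#' @param params an [sketch_params()] object.
#' @param track_cardinality store the exact distinct-k-mer count.
#' @param name sample label; defaults to the file name.
#' @return An `fmh_sketch`.
#' @export
sketch_from_file <- function(path, params, track_cardinality = FALSE,
                             name = basename(path)) {
  stopifnot(inherits(params, "fmh_params"))
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- detect_sequence_format(path)
  if (is.na(fmt)) {
    warning("file '", path, "' contains no sequence records; empty sketch")
    return(new_sketch(character(0), params, name = name,
                      source_cardinality = if (track_cardinality) 0))
  }
  seqs <- tryCatch(
    as.character(Biostrings::readDNAStringSet(path, format = fmt)),
    error = function(e) stop("could not read '", path, "' as ", fmt, ": ",
                             conditionMessage(e)))
  if (length(seqs) == 0L)
    warning("file '", path, "' contains no sequence records; empty sketch")
  res <- cpp_sketch_sequences(seqs, params$k, params$hash_seed,
                              params$scale_factor, track_cardinality)
  new_sketch(res$hashes, params, name = name,
             source_cardinality = if (track_cardinality) res$n_distinct)
}

# first non-blank character decides the format; NA for an empty file
detect_sequence_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) return(NA_character_)
    line <- sub("^\\s+", "", line)
    if (nzchar(line)) {
      first <- substr(line, 1L, 1L)
      if (first == ">") return("fasta")
      if (first == "@") return("fastq")
      stop("cannot detect sequence format of '", path,
           "': first record starts with '", first, "', expected '>' or '@'")
    }
  }
}

#' @export
print.fmh_sketch <- function(x, ...) {
  cat(sprintf("FracMinHash sketch%s: %d hashes (k = %d, s = %g, seed = %d)\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              length(x$hashes), x$params$k, x$params$scale_factor,
              x$params$hash_seed))
  if (!is.null(x$source_cardinality))
    cat(sprintf("  exact source cardinality: %g distinct k-mers\n",
                x$source_cardinality))
  invisible(x)
}

#' @export
length.fmh_sketch <- function(x) length(x$hashes)

check_compatible <- function(a, b) {
  stopifnot(inherits(a, "fmh_sketch"), inherits(b, "fmh_sketch"))
  for (field in c("k", "scale_factor", "hash_seed")) {
    if (!identical(a$params[[field]], b$params[[field]]))
      stop("incompatible sketches: '", field, "' differs (",
           a$params[[field]], " vs ", b$params[[field]], ")")
  }
  invisible(TRUE)
}

#' Sketch set algebra
#'
#' `intersection_size()` counts hash values present in both sketches;
#' `union_size()` counts values present in either. Both require the
#' sketches to share identical parameters (k, scale factor, hash seed).
#'
#' @param a,b compatible `fmh_sketch` objects.
#' @return A non-negative count.
#' @export
intersection_size <- function(a, b) {
  check_compatible(a, b)
  cpp_u64str_intersection_size(a$hashes, b$hashes)
}

#' @rdname intersection_size
#' @export
union_size <- function(a, b) {
  check_compatible(a, b)
  length(a$hashes) + length(b$hashes) - cpp_u64str_intersection_size(a$hashes, b$hashes)
}

#' Estimate source-set cardinality from a sketch
#'
#' Since a sketch of `A` has expected size `s * |A|`, the plug-in
#' cardinality estimate is `|sketch| / s`.
#'
#' @param sketch an `fmh_sketch` with `scale_factor > 0`.
#' @return Estimated number of distinct canonical k-mers in the source set.
#' @export
estimate_cardinality <- function(sketch) {
  stopifnot(inherits(sketch, "fmh_sketch"))
  s <- sketch$params$scale_factor
  if (s <= 0)
    stop("cardinality estimate undefined at scale factor 0")
  length(sketch$hashes) / s
}

#' Read and write JSON signature files
#'
#' The on-disk format is a small JSON object with fields `name`, `k`,
#' `scale_factor`, `hash_seed`, `hashes` and optionally
#' `source_cardinality`. Hash values are stored as decimal strings, sorted
#' ascending, so 64-bit precision survives any JSON reader. Reading is a
#' strict round-trip of writing; unsorted hash lists from other writers are
#' re-sorted on read and values above the acceptance threshold are
#' rejected.
#'
#' @param sketch an `fmh_sketch`.
#' @param path file path.
#' @return `write_signature()` returns `path` invisibly; `read_signature()`
#'   returns an `fmh_sketch`.
#' @export
write_signature <- function(sketch, path) {
  stopifnot(inherits(sketch, "fmh_sketch"))
  obj <- list(name = sketch$name,
              k = sketch$params$k,
              scale_factor = sketch$params$scale_factor,
              hash_seed = sketch$params$hash_seed,
              hashes = as.list(sketch$hashes))
  if (!is.null(sketch$source_cardinality))
    obj$source_cardinality <- sketch$source_cardinality
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed signature JSON in '",
                                           path, "': ", conditionMessage(e)))
  for (field in c("k", "scale_factor", "hash_seed", "hashes")) {
    if (!field %in% names(obj))
      stop("signature file '", path, "' is missing field '", field, "'")
  }
  k <- obj$k
  s <- obj$scale_factor
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("signature field 'k' out of range in '", path, "'")
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1)
    stop("signature field 'scale_factor' out of range in '", path, "'")
  params <- sketch_params(k = k, scale_factor = s, hash_seed = obj$hash_seed)
  hashes <- as.character(unlist(obj$hashes))
  if (length(hashes)) {
    chk <- cpp_u64str_validate_sort(hashes)
    hashes <- chk$hashes
    bad <- !cpp_u64str_below_threshold(hashes, s)
    if (any(bad))
      stop("signature field 'hashes' in '", path, "' holds ", sum(bad),
           " value(s) above the acceptance threshold for scale_factor = ", s)
  }
  new_sketch(hashes, params,
             name = if (is.null(obj$name)) "" else as.character(obj$name),
             source_cardinality = obj$source_cardinality)
}
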