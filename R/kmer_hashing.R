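#' Sketching parameters
#'
#' Bundle the hashing and sketching configuration shared by every sketch:
#' the k-mer length `k`, the scale factor `s` (the fraction of the 64-bit
#' hash range that is retained), and the MurmurHash3 seed. The hash range
#' size is fixed at `H = 2^64`; a hash value `v` is kept in a sketch iff
#' `v <= floor(s * H)` (with `s = 0` keeping nothing and `s = 1` keeping
#' everything).
#'
#' @param k k-mer length, a single integer >= 1.
#' @param scale_factor scale factor `s` in `[0, 1]`. The sourmash-style
#'   `scaled` parameter corresponds to `s = 1/scaled`.
#' @param hash_seed unsigned integer seed for MurmurHash3 (default 42, the
#'   sourmash convention).
#' @return An object of class `fmh_params`.
#' @examples
#' p <- sketch_params(k = 21, scale_factor = 0.001)
#' p
#' @export
sketch_params <- function(k, scale_factor = 1, hash_seed = 42L) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != as.integer(k))
    stop("'k' must be a single integer >= 1")
  if (length(scale_factor) != 1L || is.na(scale_factor) ||
      scale_factor < 0 || scale_factor > 1)
    stop("'scale_factor' must be a single value in [0, 1]")
  if (length(hash_seed) != 1L || is.na(hash_seed) || hash_seed < 0 ||
      hash_seed != as.integer(hash_seed))
    stop("'hash_seed' must be a single non-negative integer")
  structure(
    list(k = as.integer(k), scale_factor = as.numeric(scale_factor),
         hash_seed = as.integer(hash_seed)),
    class = "fmh_params")
}

#' @export
print.fmh_params <- function(x, ...) {
  cat(sprintf("FracMinHash parameters: k = %d, scale factor = %g, hash seed = %d\n",
              x$k, x$scale_factor, x$hash_seed))
  cat(sprintf("  acceptance threshold floor(s * 2^64) = %s\n",
              hash_threshold(x$scale_factor)))
  invisible(x)
}

#' Acceptance threshold for a scale factor
#'
#' Returns `floor(s * 2^64)` as a decimal string (the value itself exceeds
#' R's integer range). Hash values at or below this threshold are retained.
#'
#' @param scale_factor scale factor in `[0, 1]`.
#' @return A decimal string.
#' @export
hash_threshold <- function(scale_factor) {
  stopifnot(length(scale_factor) == 1L, scale_factor >= 0, scale_factor <= 1)
  cpp_threshold_str(scale_factor)
}

#' Canonical form of a k-mer
#'
#' The canonical form of a DNA k-mer is the lexicographically smaller of
#' the k-mer and its reverse complement, so sketches are strand-invariant.
#' Lowercase input is uppercased first; any character outside `A,C,G,T`
#' is an error.
#'
#' @param kmer character vector of k-mers.
#' @return Character vector of canonical k-mers (idempotent:
#'   `canonicalize(canonicalize(x)) == canonicalize(x)`).
#' @examples
#' canonicalize(c("ACGT", "TTTT", "gatc"))
#' @export
canonicalize <- function(kmer) {
  if (!is.character(kmer)) stop("'kmer' must be a character vector")
  cpp_canonicalize(kmer)
}

#' Hash a canonical k-mer
#'
#' Maps a k-mer to its 64-bit hash value: the first 64 bits of the
#' MurmurHash3 x64_128 digest of the uppercase ASCII bytes, with the given
#' seed. This reproduces the hash used by sourmash and frac-kmc, so
#' sketches are exchangeable with those tools.
#'
#' @param kmer character vector of k-mers (canonicalized internally unless
#'   `canonical = FALSE`).
#' @param params an [sketch_params()] object, or `NULL` to use `seed`.
#' @param seed hash seed used when `params` is `NULL`.
#' @param canonical canonicalize before hashing (default `TRUE`).
#' @return Character vector of decimal-encoded unsigned 64-bit hash values
#'   (R doubles cannot represent all 64-bit integers exactly).
#' @examples
#' hash_kmer("ACGT")   # equals the reference MurmurHash3 x64_128 value
#' @export
hash_kmer <- function(kmer, params = NULL, seed = 42L, canonical = TRUE) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "fmh_params"))
    seed <- params$hash_seed
  }
  if (canonical) kmer <- cpp_canonicalize(kmer)
  cpp_hash_strings(kmer, as.integer(seed))
}

#' Stream canonical k-mers from a nucleotide sequence
#'
#' Yields the canonical form of every length-`k` window whose characters
#' are all in `{A,C,G,T}` after uppercasing; windows containing any other
#' character (ambiguity codes, gaps) are skipped. Sequences shorter than
#' `k` yield an empty vector.
#'
#' @param sequence a single nucleotide string.
#' @param params an [sketch_params()] object (only `k` is used), or `NULL`.
#' @param k k-mer length when `params` is `NULL`.
#' @return Character vector of canonical k-mers, in window order.
#' @examples
#' stream_kmers("ACGTA", k = 3)
#' stream_kmers("ACNGT", k = 3)  # every window hits the N: empty
#' @export
stream_kmers <- function(sequence, params = NULL, k = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "fmh_params"))
    k <- params$k
  }
  if (is.null(k)) stop("supply 'params' or 'k'")
  stopifnot(is.character(sequence), length(sequence) == 1L)
  cpp_stream_kmers(sequence, as.integer(k))
}

# internal: reverse complement of an ACGT string (used in tests/properties)
reverse_complement <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
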