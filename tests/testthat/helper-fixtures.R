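# shared fixture builders; everything is generated in code at test time

DNA <- c("A", "C", "G", "T")

random_kmers <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) paste(sample(DNA, k, TRUE), collapse = ""),
         character(1))
}

random_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(DNA, len, TRUE), collapse = "")
}

write_fasta <- function(records, path, gz = FALSE) {
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (nm in names(records))
    writeLines(c(paste0(">", nm), records[[nm]]), con)
  invisible(path)
}

write_fastq <- function(records, path, gz = FALSE) {
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (nm in names(records)) {
    writeLines(c(paste0("@", nm), records[[nm]], "+",
                 strrep("I", nchar(records[[nm]]))), con)
  }
  invisible(path)
}

# brute-force reverse complement, independent of the package C++ path
rc_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force metric formulas evaluated directly on counts; kept separate
# from the package implementation on purpose
oracle_metric <- function(metric, A, B) {
  A <- unique(A); B <- unique(B)
  i <- length(intersect(A, B)); a <- length(A); b <- length(B)
  u <- a + b - i
  switch(metric,
    jaccard = i / u,
    containment_AB = i / a,
    containment_BA = i / b,
    cosine = i / sqrt(a * b),
    kulczynski1 = i / (u - i),
    kulczynski2 = (i / a + i / b) / 2,
    whittaker = 1 - (i / a + i / b) / 2,
    sorensen = 2 * i / (a + b),
    bray_curtis = 1 - 2 * i / (a + b))
}

all_metrics <- c("jaccard", "containment_AB", "containment_BA", "cosine",
                 "kulczynski1", "kulczynski2", "whittaker", "sorensen",
                 "bray_curtis")
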