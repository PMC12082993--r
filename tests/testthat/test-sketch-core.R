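# sketch construction, file input, set algebra, serialization

test_that("scale factor 0 and 1 are the empty and complete sketches", {
  km <- random_kmers(1000, 21, seed = 21)
  s0 <- build_sketch(km, sketch_params(21, 0))
  expect_length(s0$hashes, 0)
  s1 <- build_sketch(km, sketch_params(21, 1), track_cardinality = TRUE)
  n_distinct <- length(unique(canonicalize(km)))
  expect_length(s1$hashes, n_distinct)
  expect_equal(s1$source_cardinality, n_distinct)
  expect_error(sketch_params(21, 1.5), "scale_factor")
})

test_that("sketch sizes concentrate around s * |A|", {
  n <- 10000; s <- 0.1
  reps <- 200
  set.seed(5)
  sizes <- sample_sketch_sizes(n, s, reps, element_mode = "hashed")
  # mean within 3 * sqrt(n s (1-s) / reps) of s n
  expect_lt(abs(mean(sizes) - s * n), 3 * sqrt(n * s * (1 - s) / reps))
  # and every size is within a generous Chernoff window
  expect_true(all(abs(sizes - s * n) < 0.25 * s * n))
})

test_that("sketch hashes are sorted, unique, and below the threshold", {
  km <- random_kmers(5000, 15, seed = 8)
  sk <- build_sketch(km, sketch_params(15, 0.25))
  h <- as.numeric(sk$hashes)
  expect_true(all(diff(h) > 0))
  expect_true(all(h <= 0.25 * 2^64))
  expect_false(any(duplicated(sk$hashes)))
})

test_that("scale monotonicity: smaller scale gives a subset sketch", {
  km <- random_kmers(2000, 11, seed = 13)
  scales <- c(0.05, 0.2, 0.7, 1)
  sketches <- lapply(scales, function(s)
    build_sketch(km, sketch_params(11, s)))
  for (i in seq_len(length(scales) - 1)) {
    expect_true(all(sketches[[i]]$hashes %in% sketches[[i + 1]]$hashes))
  }
})

test_that("sketching is a homomorphism over stream concatenation and intersection", {
  a <- random_kmers(400, 9, seed = 31)
  b <- random_kmers(400, 9, seed = 32)
  p <- sketch_params(9, 0.5)
  s_ab <- build_sketch(c(a, b), p)
  s_a <- build_sketch(a, p); s_b <- build_sketch(b, p)
  expect_setequal(s_ab$hashes, union(s_a$hashes, s_b$hashes))
  ca <- unique(canonicalize(a)); cb <- unique(canonicalize(b))
  s_int <- build_sketch(intersect(ca, cb), p)
  expect_setequal(s_int$hashes, intersect(s_a$hashes, s_b$hashes))
})

test_that("intersection and union sizes match brute-force set computation", {
  p <- sketch_params(7, 1)
  set.seed(17)
  for (rep in 1:5) {
    a <- unique(canonicalize(random_kmers(150, 7)))
    b <- unique(canonicalize(random_kmers(150, 7)))
    s_a <- build_sketch(a, p); s_b <- build_sketch(b, p)
    expect_equal(intersection_size(s_a, s_b), length(intersect(a, b)))
    expect_equal(union_size(s_a, s_b), length(union(a, b)))
    expect_equal(union_size(s_a, s_b),
                 length(s_a) + length(s_b) - intersection_size(s_a, s_b))
  }
  s_a <- build_sketch(unique(canonicalize(random_kmers(100, 7))), p)
  expect_equal(intersection_size(s_a, s_a), length(s_a))
  mism <- build_sketch("ACGTACG", sketch_params(7, 0.5))
  expect_error(intersection_size(s_a, mism), "scale_factor")
})

test_that("cardinality estimation inverts the expected sketch size", {
  km <- unique(canonicalize(random_kmers(600, 13, seed = 41)))
  s1 <- build_sketch(km, sketch_params(13, 1))
  expect_equal(estimate_cardinality(s1), length(km))
  s0 <- build_sketch(km, sketch_params(13, 0))
  expect_error(estimate_cardinality(s0), "scale factor 0")
  # Monte-Carlo: |A| = 20000, s = 0.05, mean estimate within 3 SE
  n <- 20000; s <- 0.05; reps <- 300
  set.seed(6)
  sizes <- sample_sketch_sizes(n, s, reps, element_mode = "hashed")
  se <- sqrt((1 - s) * n / s) / sqrt(reps)
  expect_lt(abs(mean(sizes / s) - n), 3 * se)
})

test_that("FASTA, FASTQ and gzip inputs produce identical sketches", {
  p <- sketch_params(5, 1)
  recs <- list(r1 = random_dna(80, seed = 51), r2 = random_dna(60))
  fa <- tempfile(fileext = ".fa"); write_fasta(recs, fa)
  fq <- tempfile(fileext = ".fq"); write_fastq(recs, fq)
  fagz <- tempfile(fileext = ".fa.gz"); write_fasta(recs, fagz, gz = TRUE)
  sk_fa <- sketch_from_file(fa, p, track_cardinality = TRUE)
  sk_fq <- sketch_from_file(fq, p)
  sk_gz <- sketch_from_file(fagz, p)
  expect_identical(sk_fa$hashes, sk_fq$hashes)
  expect_identical(sk_fa$hashes, sk_gz$hashes)
  # hand-enumerated distinct canonical k-mer count
  kmers <- unique(c(canonicalize(substring(recs$r1, 1:76, 5:80)),
                    canonicalize(substring(recs$r2, 1:56, 5:60))))
  expect_length(sk_fa$hashes, length(kmers))
  expect_equal(sk_fa$source_cardinality, length(kmers))
  expect_identical(sort(sk_fa$hashes), sort(hash_kmer(kmers)))
})

test_that("file-format detection handles edge cases", {
  p <- sketch_params(3, 1)
  empty <- tempfile(); file.create(empty)
  expect_warning(sk <- sketch_from_file(empty, p), "no sequence records")
  expect_length(sk$hashes, 0)
  garbled <- tempfile(); writeLines("not a sequence file", garbled)
  expect_error(sketch_from_file(garbled, p), "cannot detect")
  expect_error(sketch_from_file(tempfile(), p), "not found")
})

test_that("signature files round-trip exactly", {
  km <- random_kmers(300, 21, seed = 61)
  sk <- build_sketch(km, sketch_params(21, 0.8), track_cardinality = TRUE,
                     name = "sample-x")
  path <- tempfile(fileext = ".sig")
  write_signature(sk, path)
  rt <- read_signature(path)
  expect_identical(rt$hashes, sk$hashes)
  expect_identical(rt$params, sk$params)
  expect_identical(rt$name, sk$name)
  expect_equal(rt$source_cardinality, sk$source_cardinality)
  # stored sorted ascending as decimal strings
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_type(raw$hashes, "character")
  expect_false(is.unsorted(as.numeric(raw$hashes)))
})

test_that("signature reader rejects malformed input with a field name", {
  path <- tempfile(fileext = ".sig")
  jsonlite::write_json(list(name = "x", k = 21, hash_seed = 42,
                            hashes = list()),
                       path, auto_unbox = TRUE)
  expect_error(read_signature(path), "scale_factor")
  jsonlite::write_json(list(name = "x", k = 21, scale_factor = 0.001,
                            hash_seed = 42,
                            hashes = list("18446744073709551615")),
                       path, auto_unbox = TRUE)
  expect_error(read_signature(path), "threshold")
  writeLines("{ not json", path)
  expect_error(read_signature(path), "malformed")
})
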