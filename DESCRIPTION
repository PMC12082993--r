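Package: fracminhash
Title: FracMinHash Sketching and Similarity Estimation for k-mer Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fractional MinHash (FracMinHash) sketching of DNA k-mer sets
    and the estimation theory that goes with it. Builds sourmash-compatible
    sketches (canonical k-mers, MurmurHash3 x64_128, scale factor s) from
    FASTA/FASTQ files, computes plug-in and bias-corrected estimators of
    set similarity and dissimilarity measures (Jaccard, containment,
    cosine, Kulczynski, Sorensen, Bray-Curtis, Whittaker), provides
    Chernoff-bound error guarantees and a recommended minimum scale factor
    for a desired error tolerance and confidence, and includes a simulation
    harness for validating estimator coverage and unbiasedness on random
    set pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
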