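# exact set metrics, plug-in estimates, bias corrections

test_that("worked example: A = {1..6}, B = {4..9}", {
  A <- 1:6; B <- 4:9
  expected <- c(jaccard = 1 / 3, containment_AB = 0.5, containment_BA = 0.5,
                cosine = 0.5, kulczynski1 = 0.5, kulczynski2 = 0.5,
                whittaker = 0.5, sorensen = 0.5, bray_curtis = 0.5)
  for (m in names(expected)) {
    expect_equal(metric_on_sets(A, B, m)$value, unname(expected[m]),
                 info = m)
  }
})

test_that("identity and disjoint cases hit the boundary values", {
  A <- letters[1:10]
  for (m in c("cosine", "jaccard", "containment_AB", "sorensen",
              "kulczynski2")) {
    expect_equal(metric_on_sets(A, A, m)$value, 1, info = m)
  }
  expect_equal(metric_on_sets(A, A, "bray_curtis")$value, 0)
  expect_equal(metric_on_sets(A, A, "whittaker")$value, 0)
  expect_identical(metric_on_sets(A, A, "kulczynski1")$value, Inf)
  B <- letters[11:20]
  for (m in c("cosine", "jaccard", "sorensen", "kulczynski1",
              "kulczynski2")) {
    expect_equal(metric_on_sets(A, B, m)$value, 0, info = m)
  }
  expect_equal(metric_on_sets(A, B, "bray_curtis")$value, 1)
  expect_equal(metric_on_sets(A, B, "whittaker")$value, 1)
  expect_error(metric_on_sets(character(0), A, "cosine"), "undefined")
  expect_error(metric_on_sets(character(0), character(0), "jaccard"),
               "undefined")
})

test_that("set metrics agree with an independent brute-force oracle", {
  set.seed(71)
  for (rep in 1:10) {
    A <- sample(1:60, sample(5:40, 1))
    B <- sample(1:60, sample(5:40, 1))
    for (m in all_metrics) {
      got <- metric_on_sets(A, B, m)$value
      expect_equal(got, oracle_metric(m, A, B), info = m)
    }
  }
})

test_that("plug-in at s = 1 equals the exact set computation", {
  p <- sketch_params(8, 1)
  set.seed(81)
  for (rep in 1:5) {
    A <- unique(canonicalize(random_kmers(120, 8)))
    B <- unique(canonicalize(c(sample(A, 40), random_kmers(80, 8))))
    s_a <- build_sketch(A, p); s_b <- build_sketch(B, p)
    for (m in all_metrics) {
      expect_equal(plug_in_metric(s_a, s_b, m)$value,
                   metric_on_sets(A, B, m)$value, info = m)
    }
  }
})

test_that("plug-in symmetry and algebraic identities hold on sketches", {
  p <- sketch_params(8, 0.6)
  set.seed(91)
  A <- random_kmers(500, 8); B <- c(sample(A, 200), random_kmers(300, 8))
  s_a <- build_sketch(A, p); s_b <- build_sketch(B, p)
  for (m in setdiff(all_metrics, c("containment_AB", "containment_BA"))) {
    expect_equal(plug_in_metric(s_a, s_b, m)$value,
                 plug_in_metric(s_b, s_a, m)$value, info = m)
  }
  expect_equal(plug_in_metric(s_a, s_b, "containment_AB")$value,
               plug_in_metric(s_b, s_a, "containment_BA")$value)
  k2 <- plug_in_metric(s_a, s_b, "kulczynski2")$value
  expect_equal(plug_in_metric(s_a, s_b, "whittaker")$value, 1 - k2)
  so <- plug_in_metric(s_a, s_b, "sorensen")$value
  expect_equal(plug_in_metric(s_a, s_b, "bray_curtis")$value, 1 - so)
  j <- plug_in_metric(s_a, s_b, "jaccard")$value
  expect_equal(plug_in_metric(s_a, s_b, "kulczynski1")$value, j / (1 - j))
  expect_equal(plug_in_metric(s_a, s_a, "cosine")$value, 1)
})

test_that("empty sketches degrade to limiting values with a warning", {
  p <- sketch_params(9, 1e-12)  # threshold so low the sketches are empty
  s_a <- build_sketch(random_kmers(50, 9, seed = 1), p)
  s_b <- build_sketch(random_kmers(50, 9, seed = 2), p)
  expect_length(s_a$hashes, 0)
  expect_warning(v <- plug_in_metric(s_a, s_b, "cosine")$value, "degenerate")
  expect_equal(v, 0)
  expect_warning(v <- plug_in_metric(s_a, s_b, "bray_curtis")$value,
                 "degenerate")
  expect_equal(v, 1)
})

test_that("corrections reduce to the plug-in at s = 1 and preserve identities", {
  p <- sketch_params(8, 1)
  A <- unique(canonicalize(random_kmers(150, 8, seed = 3)))
  B <- unique(canonicalize(c(sample(A, 60), random_kmers(100, 8))))
  s_a <- build_sketch(A, p, track_cardinality = TRUE)
  s_b <- build_sketch(B, p, track_cardinality = TRUE)
  for (m in c("jaccard", "containment_AB", "kulczynski2", "whittaker")) {
    expect_equal(suppressMessages(corrected_estimate(s_a, s_b, m))$value,
                 plug_in_metric(s_a, s_b, m)$value, info = m)
  }
  # Whittaker-hat is 1 - K2-hat by construction, at any scale
  p2 <- sketch_params(8, 0.3)
  t_a <- build_sketch(A, p2, track_cardinality = TRUE)
  t_b <- build_sketch(B, p2, track_cardinality = TRUE)
  expect_equal(corrected_estimate(t_a, t_b, "whittaker")$value,
               1 - corrected_estimate(t_a, t_b, "kulczynski2")$value)
  expect_error(corrected_estimate(t_a, t_b, "cosine"))
  s0 <- build_sketch(A, sketch_params(8, 0), track_cardinality = TRUE)
  expect_error(corrected_estimate(s0, s0, "jaccard"), "scale factor 0")
})

test_that("missing cardinalities fall back to sketch estimates with a notice", {
  p <- sketch_params(8, 0.5)
  s_a <- build_sketch(random_kmers(400, 8, seed = 4), p)
  s_b <- build_sketch(random_kmers(400, 8, seed = 5), p)
  expect_message(corrected_estimate(s_a, s_b, "containment_AB"),
                 "sketch estimate")
  expect_silent(corrected_estimate(s_a, s_b, "containment_AB",
                                   cardinality_a = 400))
})

test_that("corrected estimators are unbiased and the plug-in shows the predicted bias", {
  # small union so the bias factor 1 - (1-s)^{|A u B|} is far from 1
  n_a <- 300; n_b <- 300; n_i <- 150; s <- 0.005
  true_j <- n_i / (n_a + n_b - n_i)
  bias_factor <- 1 - (1 - s)^(n_a + n_b - n_i)  # about 0.895
  reps <- 2000
  corr <- unbiasedness_experiment("jaccard", n_a, n_b, n_i, s,
                                  repetitions = reps, seed = 9)
  expect_equal(corr$true_value, true_j)
  expect_lt(abs(corr$mc_mean - true_j), 3 * corr$mc_se)
  plain <- unbiasedness_experiment("jaccard", n_a, n_b, n_i, s,
                                   repetitions = reps, seed = 9,
                                   corrected = FALSE)
  expect_lt(abs(plain$mc_mean - true_j * bias_factor), 3 * plain$mc_se)
  # the biased mean sits well below the truth
  expect_lt(plain$mc_mean + 3 * plain$mc_se, true_j)
})
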