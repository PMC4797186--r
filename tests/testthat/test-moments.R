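test_that("expected counts and entropies follow the stationary formulas", {
  m0 <- uniform_m0()
  expect_equal(expected_count(m0, "AA", 10), 9 / 16)
  expect_equal(expected_count(m0, "ACG", 3), word_probability(m0, "ACG"))
  pi <- matrix(0.1, 4, 4); diag(pi) <- 0.7
  m1 <- background_model(c(0.5, 0.2, 0.2, 0.1), pi = pi, order = 1L)
  expect_equal(expected_count(m1, "AA", 3), 2 * 0.35)

  expect_equal(expected_entropy(m0, "AA", rep(1, 2), 10),
               (10 * 0.25 + 9 * 0.0625) / 2)
  expect_equal(expected_entropy(m0, "AA", c(0, 1), 10),
               expected_count(m0, "AA", 10))
})

test_that("expected entropy agrees with a Monte-Carlo mean", {
  m0 <- uniform_m0()
  ws <- gaussian_weights(2, 1.5)
  n <- 20000; l <- 50
  withr::with_seed(31, {
    X <- matrix(sample.int(4, n * l, replace = TRUE) - 1L, n, l)
    cnt <- function(wc) {
      k <- length(wc); s <- numeric(n)
      for (i in 1:(l - k + 1)) {
        mm <- X[, i] == wc[1]
        if (k > 1) for (j in 2:k) mm <- mm & X[, i + j - 1] == wc[j]
        s <- s + mm
      }
      s
    }
    a <- ws$weights
    se <- (a[1] * cnt(0L) + a[2] * cnt(c(0L, 0L))) / sum(a)
    expect_lt(abs(mean(se) - expected_entropy(m0, "AA", ws, l)),
              3 * sd(se) / sqrt(n))
  })
})

test_that("overlap indicators encode the shift geometry", {
  expect_equal(overlap_indicator("ATA", 1), 1L)
  expect_equal(overlap_indicator("AATA", 2), 0L)
  for (u in 0:4) expect_equal(overlap_indicator("AAAA", u), 1L)
  expect_error(overlap_indicator("ATA", 4), "integer")

  expect_equal(overlap_indicator_left("CA", "AGC", 1), 1L)
  expect_equal(overlap_indicator_left("CA", "GGC", 1), 0L)
  expect_equal(overlap_indicator_left("CA", "GGC", 0), 1L)

  expect_equal(overlap_indicator_right("AGCC", "CC", 2), 1L)
  expect_equal(overlap_indicator_right("AGCC", "GC", 3), 1L)
  expect_equal(overlap_indicator_right("AGCC", "AG", 1), 0L)
})

test_that("count variance matches the enumeration anchors", {
  m0 <- uniform_m0()
  expect_equal(count_variance(m0, "AA", 3, include_nonoverlap = TRUE), 9 / 64,
               tolerance = 1e-12)
  # single window: Bernoulli variance
  m1 <- test_m1()
  p <- word_probability(m1, "ACG")
  expect_equal(count_variance(m1, "ACG", 3, TRUE), p * (1 - p))
  # a non-self-overlapping word against the enumeration oracle
  env <- oracle_env(m0, 3)
  cw <- oracle_counts(env, code_word("AC"))
  expect_equal(count_variance(m0, "AC", 3, TRUE), oracle_cov(env, cw, cw),
               tolerance = 1e-12)
})

test_that("count covariance matches enumeration and is symmetric", {
  m0 <- uniform_m0()
  expect_equal(count_covariance(m0, "AA", "A", 2, include_nonoverlap = TRUE),
               3 / 32, tolerance = 1e-12)
  env <- oracle_env(m0, 6)
  cl <- oracle_counts(env, code_word("AC"))
  cs <- oracle_counts(env, code_word("C"))
  expect_equal(count_covariance(m0, "AC", "C", 6, TRUE),
               oracle_cov(env, cl, cs), tolerance = 1e-12)
  # argument order does not matter
  m1 <- test_m1()
  expect_identical(count_covariance(m1, "GAT", "AT", 9, TRUE),
                   count_covariance(m1, "AT", "GAT", 9, TRUE))
  expect_error(count_covariance(m0, "AC", "A", 5), "suffix")
})

test_that("entropy variance contracts the suffix covariance matrix", {
  m1 <- test_m1()
  # degenerate kernel: variance of the full-word count alone
  expect_equal(entropy_variance(m1, "GATC", c(0, 0, 0, 1), 30, TRUE),
               count_variance(m1, "GATC", 30, TRUE))
  # recomputable from stored parts: a' C a / (sum a)^2
  ws <- gaussian_weights(3, 0.8)
  wm <- word_moments(m1, "TGA", ws, 25, include_nonoverlap = TRUE)
  a <- ws$weights
  expect_equal(wm$variance, drop(a %*% wm$cov_matrix %*% a) / sum(a)^2,
               tolerance = 1e-10)
  expect_equal(wm$cov_matrix, t(wm$cov_matrix))
  expect_true(all(diag(wm$cov_matrix) >= 0))
})

test_that("entropy variance equals the exhaustive enumeration at l = 5", {
  ws <- gaussian_weights(2, 1.5)
  a <- ws$weights
  for (model in list(uniform_m0(), test_m1())) {
    env <- oracle_env(model, 5)
    for (w in words_of_length(2)) {
      c2 <- oracle_counts(env, code_word(w))
      c1 <- oracle_counts(env, code_word(substr(w, 2, 2)))
      se <- (a[1] * c1 + a[2] * c2) / sum(a)
      expect_equal(entropy_variance(model, w, ws, 5, TRUE),
                   oracle_cov(env, se, se), tolerance = 1e-10)
    }
  }
})

test_that("count variances stay non-negative with non-overlap terms on", {
  withr::with_seed(33, {
    for (model in list(uniform_m0(), skewed_m0(), test_m1())) {
      for (i in 1:10) {
        w <- random_dna(sample(2:5, 1))
        l <- sample(nchar(w):30, 1)
        expect_gte(count_variance(model, w, l, include_nonoverlap = TRUE), 0)
      }
    }
  })
})

test_that("neglected non-overlap terms stay a stable, small correction", {
  # The gapped (pi^t) sums contribute at the same O(l) order as the
  # variance itself, so their relative weight converges to a
  # chain-dependent constant as l grows: bounded for a strongly mixing
  # chain, and small for the weakly correlated models estimated from
  # random DNA that scoring actually uses.
  ws <- gaussian_weights(4, 1.5)
  rel_gap <- function(m, w, l) {
    v_on <- entropy_variance(m, w, ws, l, include_nonoverlap = TRUE)
    abs(v_on - entropy_variance(m, w, ws, l, include_nonoverlap = FALSE)) /
      v_on
  }
  m_strong <- test_m1()
  withr::with_seed(34, {
    m_weak <- estimate_model(random_dna(20000), order = 1L)
  })
  for (w in c("AAAA", "ATAT", "ACGT")) {
    gap <- vapply(c(200, 1000, 3000), function(l) rel_gap(m_strong, w, l), 0)
    expect_lt(max(gap), 0.5)
    expect_lt(abs(gap[3] - gap[2]), abs(gap[2] - gap[1]) + 1e-6)  # converges
    expect_lt(max(vapply(c(50, 200, 1000),
                         function(l) rel_gap(m_weak, w, l), 0)), 0.02)
  }
})

test_that("non-overlap terms change nothing under order-0 models", {
  # pi^t(a, b) = mu(b) for order 0, so the gapped sums vanish exactly
  m0 <- skewed_m0()
  for (w in c("AAT", "CGC")) {
    expect_equal(count_variance(m0, w, 12, TRUE),
                 count_variance(m0, w, 12, FALSE), tolerance = 1e-13)
    expect_equal(count_covariance(m0, w, substr(w, 2, 3), 12, TRUE),
                 count_covariance(m0, w, substr(w, 2, 3), 12, FALSE),
                 tolerance = 1e-13)
  }
})
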