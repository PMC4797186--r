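test_that("random sequences follow the background model", {
  m0 <- uniform_m0()
  s <- random_sequence(m0, 1e5, seed = 51)
  freq <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  # binomial 3-sigma band around 0.25
  expect_true(all(abs(freq / 1e5 - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))

  # deterministic chain
  pi <- diag(4) * 0 + diag(4)
  det <- background_model(c(1, 0, 0, 0) + 1e-12, pi = diag(4), order = 1L)
  expect_equal(random_sequence(det, 20, seed = 1),
               paste(rep("A", 20), collapse = ""))

  expect_identical(random_sequence(m0, 500, seed = 7),
                   random_sequence(m0, 500, seed = 7))

  # order-1 dinucleotide frequencies track the transition matrix
  m1 <- test_m1()
  s1 <- random_sequence(m1, 2e4, seed = 52)
  est <- estimate_model(s1, order = 1L, pseudocount = 0)
  expect_equal(unname(est$pi), unname(m1$pi), tolerance = 0.05)
})

test_that("background windows have the requested shape and come from the pool", {
  pool <- c(p1 = random_dna(1000))
  w <- sample_background_windows(pool, 1000, 1, seed = 53)
  expect_equal(unname(w), unname(pool))
  expect_error(sample_background_windows(pool, 1001, 5), "long")
  withr::with_seed(54, {
    pool <- setNames(vapply(1:3, function(i) random_dna(400), ""),
                     paste0("p", 1:3))
    ws <- sample_background_windows(pool, 120, 20, seed = 55)
    expect_length(ws, 20)
    expect_true(all(nchar(ws) == 120))
    expect_true(all(vapply(ws, function(x)
      any(vapply(pool, function(p) grepl(x, p, fixed = TRUE), TRUE)), TRUE)))
  })
})

test_that("implantation preserves length and logs verbatim implants", {
  spec0 <- implant_spec("AGCCA", 0)
  res <- implant_motifs(random_dna(200), spec0, seed = 56)
  expect_equal(nrow(res$log), 0)

  spec1 <- implant_spec("AC", 1)
  res <- implant_motifs("GGGGGG", spec1, seed = 57)
  expect_equal(res$sequence, "ACACAC")

  spec <- implant_spec(c("AGCCA", "GCCA", "TAGCCA", "CCAG", "AGCCAG"), 0.05)
  withr::with_seed(58, {
    for (i in 1:5) {
      base <- random_dna(300)
      res <- implant_motifs(base, spec)
      expect_equal(nchar(res$sequence), 300)
      for (r in seq_len(nrow(res$log))) {
        p <- res$log$position[r]; mo <- res$log$motif[r]
        expect_equal(substr(res$sequence, p, p + nchar(mo) - 1), mo)
      }
      # implants never overlap
      if (nrow(res$log) > 1) {
        ends <- res$log$position + nchar(res$log$motif) - 1
        expect_true(all(res$log$position[-1] > ends[-nrow(res$log)]))
      }
    }
  })
  expect_error(implant_spec("AC", 1.5), "0, 1")
  expect_error(implant_spec(c("AC", "ACG"), 0.1, mode = "fixed"), "equal")
})

test_that("implant counts match the skip-process expectation", {
  # E[implants] for a single motif of length lm under scan-with-skip:
  # N(j) = p (1 + N(j + lm)) + (1 - p) N(j + 1) while the motif fits
  p <- 0.01; lm <- 6L; l <- 500L
  N <- numeric(l + lm + 1)
  for (j in (l - lm + 1):1) N[j] <- p * (1 + N[j + lm]) + (1 - p) * N[j + 1]
  spec <- implant_spec("AGCCAG", p)
  withr::with_seed(59, {
    base <- random_dna(l)
    counts <- vapply(1:3000, function(i)
      nrow(implant_motifs(base, spec)$log), 0L)
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - N[1]), 3 * se)
})

test_that("experiment sets pair positives with negatives", {
  m0 <- uniform_m0()
  spec0 <- implant_spec("AGCCA", 0)
  sets <- build_experiment_sets(m0, 5, 100, spec0, seed = 60)
  expect_equal(unname(sets$positive), unname(sets$negative))
  expect_equal(length(sets$negative), 5)
  expect_true(all(nchar(sets$positive) == 100))

  sets2 <- build_experiment_sets(m0, 5, 100, spec0, seed = 60)
  expect_identical(sets2, sets)  # bit-identical reruns

  # unpaired: independent background draws
  sets3 <- build_experiment_sets(m0, 5, 100, spec0, seed = 60, paired = FALSE)
  expect_false(any(sets3$positive == sets3$negative))
})

test_that("implanted positives carry more motif content than negatives", {
  spec <- implant_spec(c("AGCCA", "GCCA", "TAGCCA", "CCAG", "AGCCAG"), 0.008)
  motif_content <- function(s) {
    sum(vapply(spec$motifs, function(m) count_occurrences(s, m), 0L))
  }
  bg <- background_model(c(0.3, 0.2, 0.2, 0.3))
  for (r in 1:10) {
    sets <- build_experiment_sets(bg, 2, 4000, spec, seed = 600 + r)
    expect_gt(motif_content(sets$positive[[1]]),
              motif_content(sets$negative[[1]]))
  }
})
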