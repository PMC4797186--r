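# independent brute-force scorers used as oracles: direct loops over
# the word universe with counts from count_occurrences()
brute_counts <- function(seq, k) {
  vapply(words_of_length(k), function(w) count_occurrences(seq, w), 0L)
}

brute_d2 <- function(A, B, k) sum(brute_counts(A, k) * brute_counts(B, k))

brute_centered <- function(seq, k, order) {
  m <- estimate_model(seq, order = order, pseudocount = 1)
  cnt <- brute_counts(seq, k)
  p <- vapply(words_of_length(k), function(w) word_probability(m, w), 0)
  list(tilde = cnt - (nchar(seq) - k + 1) * p,
       e = (nchar(seq) - k + 1) * p)
}

test_that("d2 equals the brute-force inner product", {
  expect_equal(d2("AAAA", "AAAA", 2), 9)
  expect_equal(d2("AAAA", "CCCC", 2), 0)
  withr::with_seed(41, {
    for (i in 1:3) {
      A <- random_dna(150); B <- random_dna(180)
      expect_equal(d2(A, B, 3), brute_d2(A, B, 3))
    }
  })
})

test_that("d2s and d2star match direct recomputation of their formulas", {
  withr::with_seed(42, {
    for (order in c(0L, 1L)) {
      A <- random_dna(150); B <- random_dna(200)
      ca <- brute_centered(A, 3, order); cb <- brute_centered(B, 3, order)
      den <- sqrt(ca$tilde^2 + cb$tilde^2)
      expect_equal(d2s(A, B, 3, order = order),
                   sum(ifelse(den > 0, ca$tilde * cb$tilde / den, 0)))
      expect_equal(d2star(A, B, 3, order = order),
                   sum(ca$tilde * cb$tilde / sqrt(ca$e * cb$e)))
    }
  })
})

test_that("ep2 is the inner product of entropy vectors", {
  withr::with_seed(43, {
    A <- random_dna(120); B <- random_dna(120)
    ws <- gaussian_weights(3, 0.7)
    expect_equal(ep2(A, B, 3, sigma = 0.7),
                 sum(entropy_vector(A, 3, ws) * entropy_vector(B, 3, ws)))
    expect_equal(ep2(A, B, 3, sigma = 0.7, revcomp = TRUE),
                 sum(entropy_vector(A, 3, ws, revcomp = TRUE) *
                       entropy_vector(B, 3, ws, revcomp = TRUE)))
  })
  # disjoint word content
  expect_equal(ep2("AAAA", "CCCC", 2, sigma = 0.5), 0)
})

test_that("the statistics degenerate to fixed resolution as sigma -> 0", {
  withr::with_seed(44, {
    for (i in 1:3) {
      A <- random_dna(500); B <- random_dna(500)
      expect_equal(ep2(A, B, 4, sigma = 0.01), d2(A, B, 4), tolerance = 1e-9)
      expect_equal(ep2star(A, B, 4, sigma = 0.01, variance = "poisson"),
                   d2star(A, B, 4), tolerance = 1e-6)
    }
  })
})

test_that("all measures are symmetric in their arguments", {
  withr::with_seed(45, {
    A <- random_dna(300); B <- random_dna(400)  # unequal lengths
    expect_equal(d2(A, B, 3), d2(B, A, 3), tolerance = 1e-10)
    expect_equal(d2s(A, B, 3), d2s(B, A, 3), tolerance = 1e-10)
    expect_equal(d2star(A, B, 3), d2star(B, A, 3), tolerance = 1e-10)
    expect_equal(ep2(A, B, 4), ep2(B, A, 4), tolerance = 1e-10)
    expect_equal(ep2star(A, B, 4, revcomp = TRUE),
                 ep2star(B, A, 4, revcomp = TRUE), tolerance = 1e-10)
  })
})

test_that("ep2star ranks a sequence closest to itself", {
  withr::with_seed(46, {
    A <- random_dna(400)
    self <- ep2star(A, A, 4, sigma = 0.7)
    expect_gt(self, 0)
    others <- vapply(1:50, function(i) {
      B <- paste(sample(strsplit(A, "")[[1]]), collapse = "")  # same composition
      ep2star(A, B, 4, sigma = 0.7)
    }, 0)
    expect_true(all(self > others))
  })
})

test_that("pairwise matrices are symmetric and order-invariant", {
  withr::with_seed(47, {
    seqs <- setNames(vapply(1:5, function(i) random_dna(150), ""),
                     paste0("s", 1:5))
    M <- pairwise_matrix(seqs, "ep2star", 3, sigma = 0.7, revcomp = TRUE)
    expect_equal(dim(M), c(5, 5))
    expect_equal(M, t(M))
    perm <- c(3, 1, 5, 2, 4)
    M2 <- pairwise_matrix(seqs[perm], "ep2star", 3, sigma = 0.7,
                          revcomp = TRUE)
    expect_equal(M2, M[perm, perm], ignore_attr = TRUE)
    expect_equal(length(entroprof:::.upper_scores(M)), choose(5, 2))
  })
  expect_error(pairwise_matrix(c(a = "ACGT"), "d2", 2), "at least 2")
  expect_error(pairwise_matrix(c(a = "ACGT", b = "ACGT"), "d9", 2),
               "d2")
})

test_that("score matrices serialise to matrix and long TSV", {
  withr::with_seed(48, {
    seqs <- setNames(vapply(1:4, function(i) random_dna(100), ""),
                     paste0("s", 1:4))
    M <- pairwise_matrix(seqs, "d2", 2)
    fm <- withr::local_tempfile(fileext = ".tsv")
    fl <- withr::local_tempfile(fileext = ".tsv")
    write_scores(M, fm, "matrix")
    write_scores(M, fl, "long")
    tab <- utils::read.delim(fm, comment.char = "#", row.names = 1)
    expect_equal(as.matrix(tab), M, ignore_attr = TRUE)
    lng <- utils::read.delim(fl, comment.char = "#")
    expect_equal(nrow(lng), choose(4, 2))
    expect_equal(lng$score[lng$idA == "s1" & lng$idB == "s2"], M["s1", "s2"])
  })
})
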