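# Shared helpers: an exhaustive-enumeration oracle for word-count
# moments (probability-weighted over all 4^l sequences of length l)
# and small fixture builders.  The oracle never uses the package's
# moment formulas: counts come from a direct window scan and sequence
# probabilities from the chain product.

oracle_env <- function(model, l) {
  g <- as.matrix(expand.grid(rep(list(0:3), l)))
  p <- unname(model$mu)[g[, 1] + 1]
  if (l > 1) {
    for (j in 2:l) {
      p <- p * unname(model$pi)[cbind(g[, j - 1] + 1, g[, j] + 1)]
    }
  }
  list(seqs = g, probs = p)
}

# occurrence count of word (integer codes) in every enumerated sequence
oracle_counts <- function(env, wcodes) {
  k <- length(wcodes)
  l <- ncol(env$seqs)
  cnt <- numeric(nrow(env$seqs))
  if (k > l) return(cnt)
  for (i in 1:(l - k + 1)) {
    m <- env$seqs[, i] == wcodes[1]
    if (k > 1) for (j in 2:k) m <- m & (env$seqs[, i + j - 1] == wcodes[j])
    cnt <- cnt + m
  }
  cnt
}

oracle_mean <- function(env, cnt) sum(env$probs * cnt)
oracle_cov <- function(env, c1, c2) {
  sum(env$probs * c1 * c2) - oracle_mean(env, c1) * oracle_mean(env, c2)
}

code_word <- function(w) match(strsplit(w, "")[[1]], c("A", "C", "G", "T")) - 1L

words_of_length <- function(k) {
  g <- as.matrix(expand.grid(rep(list(c("A", "C", "G", "T")), k)))
  apply(g[, k:1, drop = FALSE], 1, paste, collapse = "")
}

random_dna <- function(l, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), l, replace = TRUE, prob = probs),
        collapse = "")
}

# a first-order model whose initial distribution is the stationary
# vector of its transition matrix, as the exact moment formulas assume
stationary_m1 <- function(pi) {
  ev <- eigen(t(pi))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  background_model(v / sum(v), pi = pi, order = 1L)
}

test_m1 <- function() {
  pi <- matrix(c(0.5, 0.2, 0.2, 0.1,
                 0.1, 0.4, 0.3, 0.2,
                 0.3, 0.3, 0.2, 0.2,
                 0.2, 0.1, 0.1, 0.6), 4, 4, byrow = TRUE)
  stationary_m1(pi)
}

uniform_m0 <- function() background_model(rep(0.25, 4))
skewed_m0 <- function() background_model(c(0.4, 0.1, 0.2, 0.3))
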