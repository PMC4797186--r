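# Exact moments of word counts and simple entropies under a background
# model.
#
# Let c_{w,k} be the occurrence count of the length-k suffix of w in a
# sequence of length l generated by the model.  This module computes
#   E[c_{w,k}]               = (l - k + 1) mu(s_{w,k}),
#   Var[c_{w,k}]             (self-overlap, partial overlap and,
#                             optionally, disjoint-occurrence terms),
#   Cov[c_{w,k'}, c_{w,k''}] for the nested suffix pair (zero-shift,
#                             right/left overlapping shifts and,
#                             optionally, the two non-overlap sums),
# and contracts the resulting L x L covariance matrix with the
# resolution weights to obtain Var[SE_w].
#
# All assembled terms assume the chain is stationary (the occurrence
# probability of a word is position-independent); models estimated from
# data are treated as stationary, with the estimated letter frequency
# as the initial distribution.
#
# Every shift coefficient is the exact number of index pairs (i, j) at
# which both occurrence indicators can be non-zero; the zero-shift
# expectation carries the indicator that the shorter suffix is also a
# prefix of the longer word (without it the joint occurrence at a
# common start position is impossible):
#   zero shift           : l - k' + 1
#   right shift by d     : min(l - k' + 1, l - k'' + 1 - d)
#   left shift by d      : l - k' + 1 - d
# Dropping the non-overlap (pi^t) sums assumes occurrences separated by
# a gap are independent; it is the default for scoring and is exact for
# order-0 models, where those sums vanish identically.
#
# Internally all formulas are vectorised over 0-based word indices (see
# utils.R): the overlap indicators reduce to integer comparisons and
# the trailing transition products to ratios of precomputed mu tables,
#   prod_{j=u+1}^{k} pi(w[j-1], w[j]) = mu(w) / mu(w[1..u]).

#' Expected occurrence count of a word
#'
#' `E[c_w] = (l - |w| + 1) mu(w)` under the stationary background
#' model; 0 if the word does not fit in the sequence.
#'
#' @param model A [background_model()].
#' @param w Word over `{A,C,G,T}`.
#' @param l Sequence length.
#' @return Expected count.
#' @export
expected_count <- function(model, w, l) {
  stopifnot(inherits(model, "background_model"))
  k <- nchar(w)
  if (k > l) return(0)
  (l - k + 1) * word_probability(model, w)
}

#' Expected simple entropy of a word
#'
#' `E[SE_w] = sum_k a_k E[c_{w,k}] / sum_k a_k`, the weighted average
#' of the expected suffix counts.
#'
#' @param model A [background_model()].
#' @param w Word of length equal to the weight scheme's `L`.
#' @param weights A `weight_scheme`.
#' @param l Sequence length.
#' @return Expected entropy.
#' @export
expected_entropy <- function(model, w, weights, l) {
  w <- toupper(w)
  L <- nchar(w)
  ws <- .as_weights(weights, L)
  ec <- vapply(seq_len(L),
               function(k) expected_count(model, substr(w, L - k + 1L, L), l),
               numeric(1L))
  sum(ws$weights * ec) / sum(ws$weights)
}

#' Self-overlap indicator of a word
#'
#' 1 if the length-u suffix of `w` equals its length-u prefix (the
#' word's autocorrelation set), 0 otherwise; `u = 0` matches trivially.
#'
#' @param w Word over `{A,C,G,T}`.
#' @param u Overlap length, `0 <= u <= nchar(w)`.
#' @return 0 or 1.
#' @export
overlap_indicator <- function(w, u) {
  w <- toupper(w)
  k <- nchar(w)
  if (!.is_count(u) || u < 0 || u > k)
    stop("`u` must be an integer in [0, nchar(w)]", call. = FALSE)
  if (u == 0) return(1L)
  as.integer(substr(w, k - u + 1L, k) == substr(w, 1L, u))
}

#' Left-shift overlap indicator
#'
#' 1 if the length-u suffix of `w_short` equals the length-u prefix of
#' `w_long`: the configuration in which an occurrence of the short word
#' starts before, and overlaps the head of, the long word.
#'
#' @param w_short,w_long Words over `{A,C,G,T}`.
#' @param u Overlap length, `0 <= u <= min(nchar(w_short), nchar(w_long))`.
#' @return 0 or 1.
#' @export
overlap_indicator_left <- function(w_short, w_long, u) {
  w_short <- toupper(w_short); w_long <- toupper(w_long)
  ks <- nchar(w_short); kl <- nchar(w_long)
  if (!.is_count(u) || u < 0 || u > min(ks, kl))
    stop("`u` must be an integer in [0, min word length]", call. = FALSE)
  if (u == 0) return(1L)
  as.integer(substr(w_short, ks - u + 1L, ks) == substr(w_long, 1L, u))
}

#' Right-shift overlap indicator
#'
#' Two-branch indicator for a short word starting inside a long one.
#' For `u < nchar(w_short)`: 1 if the length-u suffix of `w_long`
#' equals the length-u prefix of `w_short` (the short word hangs off
#' the tail). For `u >= nchar(w_short)`: 1 if `w_short` occurs inside
#' `w_long` at the aligned placement starting at position
#' `nchar(w_long) - u + 1` (each shift contributes exactly one
#' placement).
#'
#' @param w_long,w_short Words over `{A,C,G,T}`.
#' @param u Shift-derived overlap length, `0 <= u <= nchar(w_long)`.
#' @return 0 or 1.
#' @export
overlap_indicator_right <- function(w_long, w_short, u) {
  w_long <- toupper(w_long); w_short <- toupper(w_short)
  kl <- nchar(w_long); ks <- nchar(w_short)
  if (!.is_count(u) || u < 0 || u > kl)
    stop("`u` must be an integer in [0, nchar(w_long)]", call. = FALSE)
  if (u < ks) {
    if (u == 0) return(1L)
    as.integer(substr(w_long, kl - u + 1L, kl) == substr(w_short, 1L, u))
  } else {
    start <- kl - u + 1L
    as.integer(substr(w_long, start, start + ks - 1L) == w_short)
  }
}

# ---- vectorised cores ------------------------------------------------
# idx: 0-based indices of words of length k (variance) or of the LONG
# word w' of length kp (covariance; w'' is its length-ks suffix).

.count_var_core <- function(model, k, l, include_nonoverlap, idx,
                            tabs = .mu_tables(model, k)) {
  if (l - k + 1 <= 0) return(rep(0, length(idx)))
  mu_k <- tabs[[k]][idx + 1]
  v <- (l - k + 1) * mu_k * (1 - mu_k)
  if (k >= 2L) {
    for (d in 1:(k - 1L)) {
      coef <- l - k + 1 - d
      if (coef <= 0) next
      u <- k - d
      eps <- (idx %% 4^u) == (idx %/% 4^d)
      prodpi <- mu_k / tabs[[k - d]][idx %/% 4^d + 1]
      v <- v + 2 * mu_k * coef * (eps * prodpi - mu_k)
    }
  }
  if (include_nonoverlap) {
    tmax <- l - 2 * k + 1
    if (tmax >= 1) {
      last <- idx %% 4
      first <- idx %/% 4^(k - 1)
      mu1 <- tabs[[1]][first + 1]
      P <- unname(model$pi)
      for (t in seq_len(tmax)) {
        pit <- P[cbind(last + 1, first + 1)]
        v <- v + 2 * mu_k^2 * (l - 2 * k - t + 2) * (pit / mu1 - 1)
        if (t < tmax) P <- P %*% unname(model$pi)
      }
    }
  }
  v
}

.count_cov_core <- function(model, kp, ks, l, include_nonoverlap, idx,
                            tabs = .mu_tables(model, kp)) {
  stopifnot(kp > ks)
  if (l - kp + 1 <= 0) return(rep(0, length(idx)))
  wpp <- idx %% 4^ks
  muP <- tabs[[kp]][idx + 1]
  muS <- tabs[[ks]][wpp + 1]
  # zero shift: both words start at the same position, so the product
  # indicator fires only when w'' is also a PREFIX of w'
  eps0 <- (idx %/% 4^(kp - ks)) == wpp
  cv <- (l - kp + 1) * (eps0 * muP - muP * muS)
  # right shifts (w'' starts d positions after w'), overlapping: d < kp
  for (d in seq_len(kp - 1L)) {
    coef <- min(l - kp + 1, l - ks + 1 - d)
    if (coef <= 0) next
    u <- kp - d
    if (u >= ks) {
      # w'' aligned wholly inside w', occupying positions d+1..d+ks
      eps <- ((idx %/% 4^(kp - d - ks)) %% 4^ks) == wpp
      term <- eps * muP - muP * muS
    } else {
      # w'' hangs off the tail of w'; conditional extension product
      pref <- wpp %/% 4^(ks - u)
      eps <- (idx %% 4^u) == pref
      prodpi <- muS / tabs[[u]][pref + 1]
      term <- eps * muP * prodpi - muP * muS
    }
    cv <- cv + coef * term
  }
  # left shifts (w'' starts d positions before w'), overlapping: d < ks
  for (d in seq_len(ks - 1L)) {
    coef <- l - kp + 1 - d
    if (coef <= 0) next
    u <- ks - d
    pref <- idx %/% 4^(kp - u)
    eps <- (wpp %% 4^u) == pref
    prodpi <- muP / tabs[[u]][pref + 1]
    cv <- cv + coef * (eps * muS * prodpi - muS * muP)
  }
  if (include_nonoverlap) {
    # gapped placements: right d >= kp (t = d - kp + 1), left d >= ks
    # (t = d - ks + 1); both ranges give t = 1 .. l - kp - ks + 1
    tmax <- l - kp - ks + 1
    if (tmax >= 1) {
      first_p <- idx %/% 4^(kp - 1)
      last_p <- idx %% 4
      first_s <- wpp %/% 4^(ks - 1)
      mu1p <- tabs[[1]][first_p + 1]
      mu1s <- tabs[[1]][first_s + 1]
      P <- unname(model$pi)
      for (t in seq_len(tmax)) {
        d_r <- kp + t - 1
        d_l <- ks + t - 1
        cv <- cv + (l - ks + 1 - d_r) * muP * muS *
          (P[cbind(last_p + 1, first_s + 1)] / mu1s - 1)
        cv <- cv + (l - kp + 1 - d_l) * muP * muS *
          (P[cbind(last_p + 1, first_p + 1)] / mu1p - 1)
        if (t < tmax) P <- P %*% unname(model$pi)
      }
    }
  }
  cv
}

#' Exact variance of a word's occurrence count
#'
#' Sums the single-window Bernoulli term, the partial self-overlap
#' terms (driven by the word's autocorrelation), and optionally the
#' disjoint-occurrence terms that couple occurrences through the
#' Markov chain.
#'
#' @param model A [background_model()].
#' @param w Word over `{A,C,G,T}`.
#' @param l Sequence length.
#' @param include_nonoverlap Include the disjoint-occurrence (pi^t)
#'   terms? With them the variance is exact; without them (the scoring
#'   default) occurrences separated by a gap are treated as
#'   independent, which is exact under order-0 models.
#' @return Variance of the count (0 if the word does not fit).
#' @export
count_variance <- function(model, w, l, include_nonoverlap = FALSE) {
  stopifnot(inherits(model, "background_model"))
  w <- toupper(w)
  k <- nchar(w)
  if (k > l) return(0)
  .count_var_core(model, k, l, include_nonoverlap, .word_to_index(w))
}

#' Exact covariance of the counts of a word and one of its suffixes
#'
#' Covariance of `c_{w'}` and `c_{w''}` where one word is a proper
#' suffix of the other (the nested pair arising from suffix counts of
#' a common word). Arguments may be given in either order.
#'
#' @param model A [background_model()].
#' @param w_long,w_short The two words; one must be a proper suffix of
#'   the other.
#' @param l Sequence length.
#' @param include_nonoverlap Include the two gapped (pi^t) sums?
#' @return Covariance of the two counts.
#' @export
count_covariance <- function(model, w_long, w_short, l,
                             include_nonoverlap = FALSE) {
  stopifnot(inherits(model, "background_model"))
  w_long <- toupper(w_long); w_short <- toupper(w_short)
  if (nchar(w_long) < nchar(w_short)) {
    tmp <- w_long; w_long <- w_short; w_short <- tmp
  }
  kp <- nchar(w_long); ks <- nchar(w_short)
  if (ks < 1L || kp == ks ||
      substr(w_long, kp - ks + 1L, kp) != w_short)
    stop("one word must be a proper suffix of the other", call. = FALSE)
  if (kp > l) return(0)
  .count_cov_core(model, kp, ks, l, include_nonoverlap, .word_to_index(w_long))
}

#' Exact variance of the simple entropy of a word
#'
#' Assembles the L x L covariance matrix of the suffix counts of `w`
#' (variances on the diagonal, suffix-pair covariances off it) and
#' contracts it with the resolution weights:
#' `Var[SE_w] = a' C a / (sum a)^2`. When the non-overlap terms are
#' dropped the assembled variance can, in corner cases, fall below
#' zero; it is then clipped to `var_floor` with a warning.
#'
#' @param model A [background_model()].
#' @param w Word of length equal to the weight scheme's `L`.
#' @param weights A `weight_scheme`.
#' @param l Sequence length.
#' @param include_nonoverlap Include the gapped (pi^t) terms?
#' @param var_floor Lower clip for the assembled variance.
#' @return Non-negative variance of `SE_w`.
#' @export
entropy_variance <- function(model, w, weights, l,
                             include_nonoverlap = FALSE, var_floor = 1e-12) {
  w <- toupper(w)
  L <- nchar(w)
  ws <- .as_weights(weights, L)
  C <- .entropy_cov_matrix(model, w, l, include_nonoverlap)
  a <- ws$weights
  v <- drop(a %*% C %*% a) / sum(a)^2
  if (v < 0) {
    warning("assembled entropy variance ", format(v), " for word ", w,
            " clipped to ", format(var_floor),
            " (non-overlap terms neglected)", call. = FALSE)
    v <- var_floor
  }
  v
}

# covariance matrix of the suffix counts c_{w,1..L}
.entropy_cov_matrix <- function(model, w, l, include_nonoverlap = FALSE) {
  L <- nchar(w)
  tabs <- .mu_tables(model, L)
  C <- matrix(0, L, L)
  for (k in seq_len(L)) {
    sk <- .word_to_index(substr(w, L - k + 1L, L))
    C[k, k] <- .count_var_core(model, k, l, include_nonoverlap, sk, tabs)
  }
  if (L >= 2L) {
    for (kp in 2:L) {
      skp <- .word_to_index(substr(w, L - kp + 1L, L))
      for (ks in 1:(kp - 1L)) {
        C[kp, ks] <- C[ks, kp] <-
          .count_cov_core(model, kp, ks, l, include_nonoverlap, skp, tabs)
      }
    }
  }
  C
}

#' Full moment summary of one word
#'
#' Convenience wrapper returning the expected suffix counts, the suffix
#' covariance matrix, and the expectation and variance of `SE_w`.
#'
#' @inheritParams entropy_variance
#' @return A list with elements `word`, `expected_counts`,
#'   `cov_matrix`, `expectation`, `variance`, `include_nonoverlap`.
#' @export
word_moments <- function(model, w, weights, l, include_nonoverlap = FALSE) {
  w <- toupper(w)
  L <- nchar(w)
  ws <- .as_weights(weights, L)
  ec <- vapply(seq_len(L),
               function(k) expected_count(model, substr(w, L - k + 1L, L), l),
               numeric(1L))
  list(word = w,
       expected_counts = ec,
       cov_matrix = .entropy_cov_matrix(model, w, l, include_nonoverlap),
       expectation = sum(ws$weights * ec) / sum(ws$weights),
       variance = entropy_variance(model, w, ws, l, include_nonoverlap),
       include_nonoverlap = include_nonoverlap)
}

# ---- whole-universe moment tables (used by EP2*) ---------------------
# Returns E[SE_w] and Var[SE_w] for every word of length L, vectorised.
.entropy_moment_table <- function(model, L, weights, l,
                                  include_nonoverlap = FALSE,
                                  var_floor = 1e-12, need_var = TRUE) {
  tabs <- .mu_tables(model, L)
  idx <- 0:(4^L - 1)
  a <- weights$weights
  A <- sum(a)
  E <- numeric(4^L)
  for (k in seq_len(L)) {
    E <- E + a[k] * max(l - k + 1, 0) * tabs[[k]][idx %% 4^k + 1]
  }
  E <- E / A
  if (!need_var) return(list(E = E, V = NULL))
  V <- numeric(4^L)
  for (k in seq_len(L)) {
    if (a[k] == 0) next
    vk <- .count_var_core(model, k, l, include_nonoverlap, 0:(4^k - 1), tabs)
    V <- V + a[k]^2 * vk[idx %% 4^k + 1]
  }
  if (L >= 2L) {
    for (kp in 2:L) {
      for (ks in 1:(kp - 1L)) {
        if (a[kp] == 0 || a[ks] == 0) next
        ck <- .count_cov_core(model, kp, ks, l, include_nonoverlap,
                              0:(4^kp - 1), tabs)
        V <- V + 2 * a[kp] * a[ks] * ck[idx %% 4^kp + 1]
      }
    }
  }
  V <- V / A^2
  neg <- V < 0
  if (any(neg)) {
    warning(sum(neg), " assembled entropy variance(s) below 0 clipped to ",
            format(var_floor), " (non-overlap terms neglected)",
            call. = FALSE)
    V[neg] <- var_floor
  }
  list(E = E, V = V)
}
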