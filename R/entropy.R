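# Simple entropies and the per-position Entropic Profile.
#
# The simple entropy SE_w of a word w of length L is the weighted
# average of the occurrence counts of all suffixes of w,
#   SE_w = sum_k a_k c_{w,k} / sum_k a_k,
# the multi-resolution analogue of a k-mer count.  The per-position
# profile is the classical single-sequence Entropic Profile: a
# geometric-weighted suffix-count sum at every position, standardised
# over the sequence.

#' Simple entropy of one word from its suffix counts
#'
#' @param suffix_counts Vector `(c_{w,1}, ..., c_{w,L})` of suffix
#'   occurrence counts, e.g. from [suffix_counts()].
#' @param weights A `weight_scheme` (or numeric vector) of matching
#'   length.
#' @return The weighted average `sum(a_k c_{w,k}) / sum(a_k)`.
#' @export
simple_entropy <- function(suffix_counts, weights) {
  L <- length(suffix_counts)
  if (L < 1L) stop("`suffix_counts` must be non-empty", call. = FALSE)
  ws <- .as_weights(weights, L)
  sum(ws$weights * suffix_counts) / sum(ws$weights)
}

# SE values for the full 4^L word universe (unnamed, indexed by the
# 0-based word index)
.se_vector <- function(codes, L, weights) {
  cnts <- .count_vectors(codes, L)
  idx <- 0:(4^L - 1)
  a <- weights$weights
  se <- numeric(4^L)
  for (k in seq_len(L)) {
    se <- se + a[k] * cnts[[k]][idx %% 4^k + 1]
  }
  se / sum(a)
}

# reverse-complement class structure for word length L:
#  rep: 0-based indices of canonical representatives (lexicographic
#       minimum of {w, rc(w)}); partner: their reverse complements
.rc_classes <- function(L) {
  idx <- 0:(4^L - 1)
  rc <- .rc_index(idx, L)
  keep <- idx <= rc
  list(rep = idx[keep], partner = rc[keep])
}

#' Entropy vector of a sequence
#'
#' Computes `SE_w` for every word `w` in the 4^L word universe. With
#' `revcomp = TRUE` the universe collapses to canonical
#' reverse-complement classes (lexicographic minimum representative)
#' and the class value is the maximum of the entropies of the word and
#' its reverse complement, so only the strongest strand signal is kept.
#'
#' @param seq DNA sequence.
#' @param L Word length (resolution), at most 10.
#' @param weights A `weight_scheme` with the same `L`.
#' @param revcomp Collapse to reverse-complement classes?
#' @return Named numeric vector of entropies (words, or class
#'   representatives).
#' @export
#' @examples
#' entropy_vector("AAAA", 2, gaussian_weights(2, 100))[["AA"]]
entropy_vector <- function(seq, L, weights, revcomp = FALSE) {
  seq <- .normalize_seq(seq)
  codes <- .encode_dna(seq)
  if (!.is_count(L) || L < 1L) stop("`L` must be a positive integer",
                                    call. = FALSE)
  if (L > length(codes)) stop("`L` exceeds the sequence length", call. = FALSE)
  if (L > 10L) stop("full-universe entropy vectors are limited to L <= 10",
                    call. = FALSE)
  ws <- .as_weights(weights, L)
  se <- .se_vector(codes, L, ws)
  if (revcomp) {
    cls <- .rc_classes(L)
    val <- pmax(se[cls$rep + 1], se[cls$partner + 1])
    names(val) <- .all_words(L)[cls$rep + 1]
    val
  } else {
    stats::setNames(se, .all_words(L))
  }
}

#' Per-position Entropic Profile of a sequence
#'
#' For each position i, the raw profile is
#' `f(i) = (1 + (1/l) * sum_{k=1}^{L} 4^k phi^k c([i-k+1, i])) /
#' sum_{k=0}^{L} phi^k`, where `c([i-k+1, i])` counts the occurrences
#' in the whole sequence of the length-k suffix ending at i; positions
#' `i < L` use only the suffixes that fit. The standardised profile
#' subtracts the arithmetic mean and divides by the standard deviation
#' (n-1 denominator) of the raw values; a constant raw profile yields
#' standardised values of 0 and is flagged as degenerate.
#'
#' @param seq DNA sequence.
#' @param L Maximum suffix length.
#' @param phi Positive smoothing parameter.
#' @return A data frame with columns `position`, `f_hat`, `ep`, and
#'   attributes `mean`, `sd`, `degenerate`.
#' @export
position_profile <- function(seq, L, phi) {
  seq <- .normalize_seq(seq)
  codes <- .encode_dna(seq)
  l <- length(codes)
  if (!.is_count(L) || L < 1L) stop("`L` must be a positive integer",
                                    call. = FALSE)
  if (L > l) stop("`L` exceeds the sequence length", call. = FALSE)
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0)
    stop("`phi` must be positive", call. = FALSE)
  roll <- .rolling_indices(codes, L)
  cnts <- lapply(seq_len(L), function(k) tabulate(roll[[k]] + 1, nbins = 4^k))
  num <- numeric(l)
  for (k in seq_len(L)) {
    # suffix of length k ends at positions k..l; its window starts at i-k+1
    pos <- k:l
    ck <- cnts[[k]][roll[[k]][pos - k + 1] + 1]
    ck[is.na(ck)] <- 0  # suffix touches an N: no countable occurrence
    num[pos] <- num[pos] + 4^k * phi^k * ck
  }
  f_hat <- (1 + num / l) / sum(phi^(0:L))
  m <- mean(f_hat)
  s <- stats::sd(f_hat)
  degenerate <- !is.finite(s) || s < 1e-14
  ep <- if (degenerate) rep(0, l) else (f_hat - m) / s
  out <- data.frame(position = seq_len(l), f_hat = f_hat, ep = ep)
  attr(out, "mean") <- m
  attr(out, "sd") <- if (degenerate) 0 else s
  attr(out, "degenerate") <- degenerate
  out
}
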