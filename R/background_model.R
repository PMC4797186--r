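# Background models of DNA composition.
#
# A background model is either a stationary Bernoulli model (order 0)
# or a first-order Markov chain (order 1).  Both are represented with a
# base distribution mu over {A,C,G,T} and a 4x4 row-stochastic
# transition matrix pi; for order 0 every row of pi equals mu, so all
# downstream moment formulas share a single evaluation path.

#' Construct a background model
#'
#' @param mu Numeric vector of 4 base probabilities (A, C, G, T order);
#'   normalised to sum to 1.
#' @param pi 4x4 row-stochastic transition matrix (order 1). Ignored for
#'   `order = 0`, where each row is set to `mu`.
#' @param order Markov order, 0 or 1.
#' @param pseudocount Pseudocount recorded from estimation (metadata).
#' @return An object of class `background_model`.
#' @export
background_model <- function(mu, pi = NULL, order = if (is.null(pi)) 0L else 1L,
                             pseudocount = 0) {
  if (!order %in% c(0L, 1L)) stop("`order` must be 0 or 1", call. = FALSE)
  if (length(mu) != 4L || any(mu < 0) || sum(mu) <= 0)
    stop("`mu` must be 4 non-negative probabilities", call. = FALSE)
  mu <- mu / sum(mu)
  names(mu) <- DNA_BASES
  if (order == 0L) {
    pi <- matrix(rep(mu, each = 4L), 4L, 4L)
  } else {
    if (is.null(pi) || !is.matrix(pi) || any(dim(pi) != 4L) || any(pi < 0))
      stop("order-1 model needs a 4x4 non-negative transition matrix",
           call. = FALSE)
    rs <- rowSums(pi)
    if (any(rs <= 0))
      stop("every transition-matrix row must have positive mass", call. = FALSE)
    pi <- pi / rs
  }
  dimnames(pi) <- list(DNA_BASES, DNA_BASES)
  structure(list(order = as.integer(order), mu = mu, pi = pi,
                 pseudocount = pseudocount),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("background_model (order ", x$order, ", pseudocount ", x$pseudocount,
      ")\n", sep = "")
  cat("mu:", paste(sprintf("%s=%.4f", DNA_BASES, x$mu), collapse = " "), "\n")
  if (x$order == 1L) {
    cat("pi:\n")
    print(round(x$pi, 4))
  }
  invisible(x)
}

#' Estimate a background model from a sequence
#'
#' Base probabilities are letter frequencies over non-N positions with
#' an additive pseudocount; order-1 transitions are dinucleotide
#' frequencies (pairs spanning an N are excluded), row-normalised with
#' the same pseudocount. A transition row with no observed mass (only
#' possible with `pseudocount = 0`) falls back to the base
#' distribution. The chain's initial distribution is taken to be the
#' estimated letter frequency, not the stationary vector of the
#' transition matrix.
#'
#' @param seq DNA sequence (character string over `{A,C,G,T,N}`).
#' @param order Markov order, 0 or 1.
#' @param pseudocount Non-negative additive smoothing count; the
#'   default 1 guarantees every word probability is positive.
#' @return A [background_model()] object.
#' @export
#' @examples
#' estimate_model("ACGT", order = 0, pseudocount = 0)$mu
estimate_model <- function(seq, order = 1L, pseudocount = 1) {
  if (!order %in% c(0L, 1L)) stop("`order` must be 0 or 1", call. = FALSE)
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop("`pseudocount` must be non-negative", call. = FALSE)
  seq <- .normalize_seq(seq)
  codes <- .encode_dna(seq)
  n_valid <- sum(!is.na(codes))
  if (n_valid < 1L)
    stop("sequence has no non-N residues", call. = FALSE)
  counts <- tabulate(codes + 1L, nbins = 4L)
  mu <- (counts + pseudocount)
  if (order == 0L)
    return(background_model(mu, order = 0L, pseudocount = pseudocount))
  if (n_valid < 2L)
    stop("order-1 estimation needs at least 2 non-N residues", call. = FALSE)
  l <- length(codes)
  from <- codes[-l]
  to <- codes[-1L]
  ok <- !is.na(from) & !is.na(to)
  di <- matrix(pseudocount, 4L, 4L)
  if (any(ok)) {
    tab <- tabulate(from[ok] * 4L + to[ok] + 1L, nbins = 16L)
    di <- di + matrix(tab, 4L, 4L, byrow = TRUE)
  }
  mu_norm <- mu / sum(mu)
  empty <- rowSums(di) == 0
  if (any(empty)) di[empty, ] <- rep(mu_norm, each = sum(empty))
  background_model(mu, pi = di, order = 1L, pseudocount = pseudocount)
}

#' Probability of a word under a background model
#'
#' Computes `mu(w) = mu(w1) * prod_j pi(w[j-1], w[j])`, the stationary
#' occurrence probability of `w` at any position.
#'
#' @param model A [background_model()].
#' @param w Word over `{A,C,G,T}`.
#' @return Probability in `[0, 1]`.
#' @export
word_probability <- function(model, w) {
  stopifnot(inherits(model, "background_model"))
  codes <- .encode_dna(toupper(w))
  if (length(codes) == 0L) stop("word must be non-empty", call. = FALSE)
  if (anyNA(codes)) stop("word must not contain N", call. = FALSE)
  p <- model$mu[[codes[1L] + 1L]]
  for (j in seq_along(codes)[-1L]) {
    p <- p * model$pi[codes[j - 1L] + 1L, codes[j] + 1L]
  }
  p
}

#' t-step transition probability
#'
#' Entry `(a, b)` of the t-th power of the transition matrix: the
#' probability that the chain is in state `b` exactly `t` steps after
#' being in state `a`. For an order-0 model this is `mu(b)` for every
#' `t`.
#'
#' @param model A [background_model()].
#' @param a,b Single letters in `{A,C,G,T}`.
#' @param t Positive integer number of steps.
#' @return Probability in `[0, 1]`.
#' @export
transition_power <- function(model, a, b, t) {
  stopifnot(inherits(model, "background_model"))
  if (!.is_count(t) || t < 1) stop("`t` must be a positive integer",
                                   call. = FALSE)
  P <- .matrix_power(model$pi, as.integer(t))
  P[toupper(a), toupper(b)]
}

# repeated squaring
.matrix_power <- function(M, t) {
  R <- diag(nrow(M))
  B <- M
  while (t > 0L) {
    if (t %% 2L == 1L) R <- R %*% B
    t <- t %/% 2L
    if (t > 0L) B <- B %*% B
  }
  dimnames(R) <- dimnames(M)
  R
}

# mu tables: tabs[[k]][i+1] = mu of the word with 0-based index i of
# length k (first letter most significant)
.mu_tables <- function(model, kmax) {
  mu <- unname(model$mu)
  Pi <- unname(model$pi)
  tabs <- vector("list", kmax)
  tabs[[1L]] <- mu
  if (kmax >= 2L) {
    for (k in 2:kmax) {
      idx <- 0:(4^k - 1)
      pref <- idx %/% 4
      tabs[[k]] <- tabs[[k - 1L]][pref + 1] *
        Pi[cbind(pref %% 4 + 1, idx %% 4 + 1)]
    }
  }
  tabs
}

#' Write a background model to a plain-text file
#'
#' Key-value format: one line per entry (`order`, `pseudocount`,
#' `mu <base> <prob>`, `pi <from> <to> <prob>`).
#'
#' @param model A [background_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "background_model"))
  lines <- c(
    paste("order", model$order),
    paste("pseudocount", format(model$pseudocount, digits = 17)),
    sprintf("mu %s %s", DNA_BASES, format(unname(model$mu), digits = 17)),
    sprintf("pi %s %s %s",
            rep(DNA_BASES, times = 4L), rep(DNA_BASES, each = 4L),
            format(model$pi[cbind(rep(1:4, times = 4L), rep(1:4, each = 4L))],
                   digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a background model written by [write_model()]
#'
#' @param path Input path.
#' @return A [background_model()].
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  tok <- strsplit(trimws(lines[nzchar(trimws(lines))]), "\\s+")
  key <- vapply(tok, `[`, "", 1L)
  order <- as.integer(tok[[which(key == "order")]][2L])
  pc <- as.numeric(tok[[which(key == "pseudocount")]][2L])
  mu <- stats::setNames(numeric(4L), DNA_BASES)
  for (t in tok[key == "mu"]) mu[t[2L]] <- as.numeric(t[3L])
  pi <- matrix(0, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  for (t in tok[key == "pi"]) pi[t[2L], t[3L]] <- as.numeric(t[4L])
  if (order == 0L) background_model(mu, order = 0L, pseudocount = pc)
  else background_model(mu, pi = pi, order = 1L, pseudocount = pc)
}
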