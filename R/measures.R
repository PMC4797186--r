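# Pairwise alignment-free similarity statistics.
#
# Fixed-resolution baselines D2, D2S, D2* operate on k-mer count
# vectors over the full 4^k word universe; the multi-resolution
# statistics EP2 and EP2* replace counts with simple entropies SE_w.
# Centering and standardisation conventions:
#   * each sequence is centred with a model estimated from itself;
#   * the D2* denominator pools the two sequences as the geometric
#     mean of the per-sequence expected counts
#     sqrt((lA-k+1) p_w^A * (lB-k+1) p_w^B), which preserves symmetry
#     for unequal lengths and reduces to the textbook (n-k+1) p_w when
#     the lengths and models agree;
#   * the EP2* denominator is, analogously, sqrt(VarA[SE_w] VarB[SE_w])
#     with each variance exact under the respective sequence's model
#     ("exact" option), or sqrt(EA[SE_w] EB[SE_w]) under a
#     Poisson-style approximation ("poisson" option) that makes EP2*
#     collapse onto D2* as sigma -> 0.

# per-sequence data for one measure; everything pair-independent
.measure_profile <- function(seq, measure, k, sigma = 0.7, order = 1L,
                             revcomp = FALSE, include_nonoverlap = FALSE,
                             pseudocount = 1, variance = "exact") {
  seq <- .normalize_seq(seq)
  codes <- .encode_dna(seq)
  l <- length(codes)
  if (!.is_count(k) || k < 1L) stop("`k` must be a positive integer",
                                    call. = FALSE)
  if (k > l) stop("resolution k = ", k, " exceeds a sequence length (", l,
                  ")", call. = FALSE)
  if (k > 10L) stop("resolutions above 10 are not supported", call. = FALSE)
  if (measure %in% c("d2", "d2s", "d2star")) {
    cnt <- .count_vectors(codes, k)[[k]]
    if (measure == "d2") return(list(x = cnt))
    model <- estimate_model(seq, order = order, pseudocount = pseudocount)
    Ec <- max(l - k + 1, 0) * .mu_tables(model, k)[[k]]
    return(list(x = cnt - Ec, e = Ec))
  }
  ws <- gaussian_weights(k, sigma)
  se <- .se_vector(codes, k, ws)
  if (measure == "ep2") {
    prof <- list(x = se)
  } else {
    model <- estimate_model(seq, order = order, pseudocount = pseudocount)
    mom <- .entropy_moment_table(model, k, ws, l,
                                 include_nonoverlap = include_nonoverlap,
                                 need_var = identical(variance, "exact"))
    prof <- list(x = se - mom$E, e = mom$E, v = mom$V)
  }
  if (revcomp) {
    # canonical class value: the argmax of SE over {w, rc(w)}; its own
    # expectation/variance follow the chosen word (ties -> representative)
    cls <- .rc_classes(k)
    take_rep <- se[cls$rep + 1] >= se[cls$partner + 1]
    pick <- ifelse(take_rep, cls$rep, cls$partner) + 1
    if (measure == "ep2") {
      prof$x <- se[pick]
    } else {
      prof$x <- se[pick] - prof$e[pick]
      prof$v <- prof$v[pick]
      prof$e <- prof$e[pick]
    }
  }
  prof
}

.pair_score <- function(pa, pb, measure, variance = "exact") {
  switch(measure,
    d2 = ,
    ep2 = sum(pa$x * pb$x),
    d2s = {
      den <- sqrt(pa$x^2 + pb$x^2)
      sum(ifelse(den > 0, pa$x * pb$x / den, 0))
    },
    d2star = sum(pa$x * pb$x / sqrt(pa$e * pb$e)),
    ep2star = {
      den <- if (identical(variance, "exact")) sqrt(pa$v * pb$v)
             else sqrt(pa$e * pb$e)
      sum(pa$x * pb$x / den)
    },
    stop("unknown measure: ", measure, call. = FALSE))
}

#' D2 statistic
#'
#' Inner product of the k-mer count vectors of two sequences.
#'
#' @param seqA,seqB DNA sequences.
#' @param k Word length.
#' @return The similarity score.
#' @export
d2 <- function(seqA, seqB, k) {
  .pair_score(.measure_profile(seqA, "d2", k),
              .measure_profile(seqB, "d2", k), "d2")
}

#' D2S statistic
#'
#' Sum over all 4^k words of `~A_w ~B_w / sqrt(~A_w^2 + ~B_w^2)`,
#' where `~X_w` is the count centred by its expectation under a model
#' estimated from the respective sequence. Words with both centred
#' counts zero contribute 0.
#'
#' @inheritParams d2
#' @param order Markov order of the per-sequence background models.
#' @param pseudocount Estimation pseudocount.
#' @return The similarity score.
#' @export
d2s <- function(seqA, seqB, k, order = 1L, pseudocount = 1) {
  .pair_score(.measure_profile(seqA, "d2s", k, order = order,
                               pseudocount = pseudocount),
              .measure_profile(seqB, "d2s", k, order = order,
                               pseudocount = pseudocount), "d2s")
}

#' D2* statistic
#'
#' Sum over all 4^k words of the centred-count product divided by the
#' pooled expected count (geometric mean across the two sequences).
#'
#' @inheritParams d2s
#' @return The similarity score.
#' @export
d2star <- function(seqA, seqB, k, order = 1L, pseudocount = 1) {
  .pair_score(.measure_profile(seqA, "d2star", k, order = order,
                               pseudocount = pseudocount),
              .measure_profile(seqB, "d2star", k, order = order,
                               pseudocount = pseudocount), "d2star")
}

#' EP2 statistic
#'
#' Multi-resolution analogue of D2: the inner product of the simple
#' entropy vectors (Gaussian resolution weights) of the two sequences,
#' over all 4^L words or over reverse-complement classes.
#'
#' @inheritParams d2
#' @param L Maximum resolution (word length).
#' @param sigma Gaussian kernel width for the resolution weights.
#' @param revcomp Combine strands by taking, per class, the maximum of
#'   the entropies of a word and its reverse complement?
#' @return The similarity score.
#' @export
ep2 <- function(seqA, seqB, L, sigma = 0.7, revcomp = FALSE) {
  .pair_score(.measure_profile(seqA, "ep2", L, sigma = sigma,
                               revcomp = revcomp),
              .measure_profile(seqB, "ep2", L, sigma = sigma,
                               revcomp = revcomp), "ep2")
}

#' EP2* statistic
#'
#' Multi-resolution analogue of D2*: entropies are centred by their
#' exact expectations and the products standardised by the pooled
#' variance term `sqrt(VarA[SE_w] VarB[SE_w])` (`variance = "exact"`),
#' or by the pooled expectation `sqrt(EA[SE_w] EB[SE_w])`
#' (`variance = "poisson"`), each computed under the model estimated
#' from the respective sequence.
#'
#' @inheritParams ep2
#' @param order Markov order of the per-sequence background models.
#' @param include_nonoverlap Include the gapped terms in the exact
#'   variances? Off by default (they are negligible at scoring scale).
#' @param variance `"exact"` or `"poisson"` denominator convention.
#' @param pseudocount Estimation pseudocount.
#' @return The similarity score.
#' @export
ep2star <- function(seqA, seqB, L, sigma = 0.7, order = 1L, revcomp = FALSE,
                    include_nonoverlap = FALSE, variance = c("exact", "poisson"),
                    pseudocount = 1) {
  variance <- match.arg(variance)
  args <- list(measure = "ep2star", k = L, sigma = sigma, order = order,
               revcomp = revcomp, include_nonoverlap = include_nonoverlap,
               pseudocount = pseudocount, variance = variance)
  .pair_score(do.call(.measure_profile, c(list(seqA), args)),
              do.call(.measure_profile, c(list(seqB), args)),
              "ep2star", variance = variance)
}

#' All pairwise scores for a set of sequences
#'
#' Computes the symmetric matrix of pair scores for one measure.
#' Per-sequence summaries (count or entropy vectors, moments) are
#' computed once per sequence, so the cost is linear in the number of
#' sequences plus a cheap inner product per pair.
#'
#' @param seqs Named character vector of at least 2 DNA sequences.
#' @param measure One of `"d2"`, `"d2s"`, `"d2star"`, `"ep2"`,
#'   `"ep2star"`.
#' @param k Resolution (k-mer length, or maximum length L for the EP
#'   measures).
#' @param ... Measure parameters passed on (`sigma`, `order`,
#'   `revcomp`, `include_nonoverlap`, `variance`, `pseudocount`).
#' @return Symmetric numeric matrix with sequence ids as dimnames and
#'   attributes `measure`, `k` and `params`. Diagonal self-scores are
#'   computed but flagged via the `diag_self` attribute.
#' @export
pairwise_matrix <- function(seqs, measure, k, ...) {
  measure <- match.arg(measure, c("d2", "d2s", "d2star", "ep2", "ep2star"))
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  dots <- list(...)
  variance <- dots$variance %||% "exact"
  if (identical(measure, "ep2star")) variance <- match.arg(variance,
                                                           c("exact", "poisson"))
  prof_args <- dots[names(dots) %in%
                      c("sigma", "order", "revcomp", "include_nonoverlap",
                        "pseudocount")]
  profs <- lapply(seqs, function(s) {
    do.call(.measure_profile,
            c(list(s, measure = measure, k = k, variance = variance),
              prof_args))
  })
  n <- length(seqs)
  M <- matrix(NA_real_, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      M[i, j] <- M[j, i] <- .pair_score(profs[[i]], profs[[j]], measure,
                                        variance = variance)
    }
  }
  attr(M, "measure") <- measure
  attr(M, "k") <- k
  attr(M, "params") <- c(list(variance = variance), prof_args)
  attr(M, "diag_self") <- TRUE
  M
}

# unordered within-set pair scores (upper triangle)
.upper_scores <- function(M) M[upper.tri(M)]

#' Write a pairwise score matrix as TSV
#'
#' Matrix format: comment header lines (`# key=value`) recording the
#' measure and parameters, then a header row of sequence ids. Long
#' format: columns `idA`, `idB`, `measure`, `k`, `score`, one row per
#' unordered pair.
#'
#' @param M Matrix from [pairwise_matrix()].
#' @param path Output path.
#' @param format `"matrix"` or `"long"`.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(M, path, format = c("matrix", "long")) {
  format <- match.arg(format)
  params <- attr(M, "params")
  hdr <- c(sprintf("# measure=%s", attr(M, "measure")),
           sprintf("# k=%s", attr(M, "k")),
           sprintf("# %s=%s", names(params),
                   vapply(params, function(p) paste(format(p), collapse = ","),
                          "")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "matrix") {
    writeLines(paste(c("id", colnames(M)), collapse = "\t"), con)
    utils::write.table(M, con, sep = "\t", quote = FALSE, col.names = FALSE,
                       row.names = TRUE)
  } else {
    pr <- which(upper.tri(M), arr.ind = TRUE)
    df <- data.frame(idA = rownames(M)[pr[, 1]], idB = colnames(M)[pr[, 2]],
                     measure = attr(M, "measure"), k = attr(M, "k"),
                     score = M[pr])
    writeLines(paste(colnames(df), collapse = "\t"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, col.names = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
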