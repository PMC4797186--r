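# Synthetic regulatory-sequence generation.
#
# Negative sets are plain background sequences (sampled from a Markov
# model, or windows cut from a user-supplied pool such as intergenic
# regions); positive sets implant a family of transcription-factor
# binding motifs into background sequences via a pattern-transfer
# process: a left-to-right scan that, at each eligible position,
# overwrites the next |m| letters with a motif with a fixed per-position
# insertion probability and then jumps past the implant, so implants
# never overlap and the sequence length is unchanged.

#' Implantation specification
#'
#' @param motifs Character vector of motifs over `{A,C,G,T}`. In
#'   `"fixed"` mode all motifs must have equal length (the classical
#'   pattern transfer model); `"revised"` mode permits variable
#'   lengths.
#' @param insertion_prob Per-position insertion probability in `[0, 1]`.
#' @param mode `"revised"` (variable-length) or `"fixed"`.
#' @return An object of class `implant_spec`.
#' @export
implant_spec <- function(motifs, insertion_prob, mode = c("revised", "fixed")) {
  mode <- match.arg(mode)
  if (length(motifs) < 1L) stop("`motifs` must be non-empty", call. = FALSE)
  motifs <- toupper(motifs)
  if (any(grepl("[^ACGT]", motifs)))
    stop("motifs must be over {A,C,G,T}", call. = FALSE)
  if (!is.numeric(insertion_prob) || length(insertion_prob) != 1L ||
      is.na(insertion_prob) || insertion_prob < 0 || insertion_prob > 1)
    stop("`insertion_prob` must be in [0, 1]", call. = FALSE)
  if (mode == "fixed" && length(unique(nchar(motifs))) != 1L)
    stop("fixed-length mode requires motifs of equal length", call. = FALSE)
  structure(list(motifs = motifs, insertion_prob = insertion_prob,
                 mode = mode),
            class = "implant_spec")
}

#' Sample a random sequence from a background model
#'
#' The first letter is drawn from the base distribution, subsequent
#' letters from the transition rows.
#'
#' @param model A [background_model()].
#' @param length Sequence length.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return A DNA string.
#' @export
random_sequence <- function(model, length, seed = NULL) {
  stopifnot(inherits(model, "background_model"))
  if (!.is_count(length) || length < 1L)
    stop("`length` must be a positive integer", call. = FALSE)
  .with_seed(seed, {
    if (model$order == 0L) {
      codes <- sample.int(4L, length, replace = TRUE, prob = model$mu) - 1L
    } else {
      cum <- t(apply(model$pi, 1L, cumsum))
      u <- stats::runif(length)
      codes <- integer(length)
      codes[1L] <- sample.int(4L, 1L, prob = model$mu) - 1L
      if (length >= 2L) {
        for (i in 2:length) {
          codes[i] <- min(findInterval(u[i], cum[codes[i - 1L] + 1L, ],
                                       left.open = TRUE), 3L)
        }
      }
    }
    .decode_dna(codes)
  })
}

#' Sample fixed-length windows from a background pool
#'
#' Windows are drawn uniformly over all valid (sequence, offset)
#' positions of the pool; windows containing N are rejected and
#' redrawn.
#'
#' @param pool Named character vector of pool sequences (e.g. from
#'   [read_fasta()]).
#' @param window Window length.
#' @param n Number of windows.
#' @param seed Optional integer seed.
#' @return Named character vector of `n` windows.
#' @export
sample_background_windows <- function(pool, window, n, seed = NULL) {
  if (!.is_count(window) || window < 1L)
    stop("`window` must be a positive integer", call. = FALSE)
  if (!.is_count(n) || n < 1L)
    stop("`n` must be a positive integer", call. = FALSE)
  pool <- vapply(pool, .normalize_seq, "")
  lens <- nchar(pool)
  offsets <- pmax(lens - window + 1L, 0L)
  if (sum(offsets) == 0L)
    stop("no pool sequence is at least ", window, " long", call. = FALSE)
  .with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      for (attempt in 1:1000) {
        s <- sample.int(length(pool), 1L, prob = offsets)
        o <- sample.int(offsets[s], 1L)
        win <- substr(pool[[s]], o, o + window - 1L)
        if (!grepl("N", win, fixed = TRUE)) break
        win <- NA_character_
      }
      if (is.na(win))
        stop("could not draw an N-free window of length ", window,
             call. = FALSE)
      out[i] <- win
    }
    names(out) <- sprintf("window%03d", seq_len(n))
    out
  })
}

#' Implant motifs into a sequence
#'
#' Scans positions left to right; at each position, with probability
#' `spec$insertion_prob`, a motif drawn uniformly from the set
#' overwrites the next letters (if it fits) and the scan jumps past
#' it. Output length always equals input length.
#'
#' @param seq DNA sequence.
#' @param spec An [implant_spec()].
#' @param seed Optional integer seed.
#' @return A list with elements `sequence` (the implanted sequence) and
#'   `log` (data frame of 1-based `position` and `motif`).
#' @export
implant_motifs <- function(seq, spec, seed = NULL) {
  stopifnot(inherits(spec, "implant_spec"))
  seq <- .normalize_seq(seq)
  l <- nchar(seq)
  if (any(nchar(spec$motifs) >= l))
    stop("every motif must be shorter than the sequence", call. = FALSE)
  .with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    pos <- integer(0)
    mot <- character(0)
    p <- 1L
    while (p <= l) {
      if (spec$insertion_prob > 0 &&
          stats::runif(1L) < spec$insertion_prob) {
        m <- spec$motifs[[sample.int(length(spec$motifs), 1L)]]
        lm <- nchar(m)
        if (p + lm - 1L <= l) {
          chars[p:(p + lm - 1L)] <- strsplit(m, "", fixed = TRUE)[[1L]]
          pos <- c(pos, p)
          mot <- c(mot, m)
          p <- p + lm
          next
        }
      }
      p <- p + 1L
    }
    list(sequence = paste(chars, collapse = ""),
         log = data.frame(position = pos, motif = mot))
  })
}

#' Build paired negative and positive sequence sets
#'
#' The negative set holds `n` background sequences; the positive set
#' implants the motif family into background sequences. With
#' `paired = TRUE` (default) positives are derived from the very same
#' background draws as the negatives; with `paired = FALSE` the
#' positive background is drawn independently (useful for null
#' experiments).
#'
#' @param background Either a [background_model()] (sequences are
#'   sampled from it) or a named character vector pool (windows are
#'   cut from it).
#' @param n Number of sequences per set (at least 2).
#' @param length Sequence length.
#' @param spec An [implant_spec()].
#' @param seed Optional master seed; all draws derive from it.
#' @param paired Derive positives from the same background draws?
#' @return A list with elements `negative`, `positive` (named character
#'   vectors) and `log` (implant log with a sequence id column).
#' @export
build_experiment_sets <- function(background, n, length, spec, seed = NULL,
                                  paired = TRUE) {
  stopifnot(inherits(spec, "implant_spec"))
  if (!.is_count(n) || n < 2L) stop("`n` must be at least 2", call. = FALSE)
  draw <- function(m, seed_off) {
    if (inherits(background, "background_model")) {
      stats::setNames(
        vapply(seq_len(m), function(i) {
          random_sequence(background, length,
                          seed = if (is.null(seed)) NULL
                                 else .derive_seed(seed, seed_off + i))
        }, ""),
        sprintf("seq%03d", seq_len(m)))
    } else {
      sample_background_windows(background, length, m,
                                seed = if (is.null(seed)) NULL
                                       else .derive_seed(seed, seed_off + 1L))
    }
  }
  negative <- draw(n, 0L)
  names(negative) <- sprintf("neg%03d", seq_len(n))
  base <- if (paired) stats::setNames(negative, sprintf("pos%03d", seq_len(n)))
          else stats::setNames(draw(n, n + 1L), sprintf("pos%03d", seq_len(n)))
  logs <- vector("list", n)
  positive <- character(n)
  for (i in seq_len(n)) {
    res <- implant_motifs(base[[i]], spec,
                          seed = if (is.null(seed)) NULL
                                 else .derive_seed(seed, 3L * n + 7L + i))
    positive[i] <- res$sequence
    if (nrow(res$log)) logs[[i]] <- cbind(id = names(base)[i], res$log)
  }
  names(positive) <- names(base)
  log <- do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
  if (is.null(log)) log <- data.frame(id = character(0),
                                      position = integer(0),
                                      motif = character(0))
  list(negative = negative, positive = positive, log = log)
}
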