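# Multi-resolution k-mer counting.
#
# Counting is hash-map style over observed words (sparse named
# vectors); windows overlapping an N are dropped from every count.
# Coordinates in the documentation are 1-based closed intervals.

#' Count (possibly overlapping) occurrences of a word
#'
#' @param seq DNA sequence over `{A,C,G,T,N}`.
#' @param w Word over `{A,C,G,T}`.
#' @return Number of occurrences; windows containing N never match. A
#'   word longer than the sequence has 0 occurrences.
#' @export
#' @examples
#' count_occurrences("AAAA", "AA")  # 3, overlaps count
count_occurrences <- function(seq, w) {
  seq <- .normalize_seq(seq)
  wcodes <- .encode_dna(toupper(w))
  if (length(wcodes) == 0L) stop("word must be non-empty", call. = FALSE)
  if (anyNA(wcodes)) stop("word must not contain N", call. = FALSE)
  codes <- .encode_dna(seq)
  k <- length(wcodes)
  l <- length(codes)
  if (k > l) return(0L)
  m <- rep(TRUE, l - k + 1L)
  for (j in seq_len(k)) {
    cj <- codes[j:(l - k + j)]
    m <- m & !is.na(cj) & cj == wcodes[j]
  }
  sum(m)
}

#' Build a multi-resolution word-count index
#'
#' Counts every word of length 1..L occurring in `seq` (sparse: absent
#' words are reported as 0 on lookup).
#'
#' @param seq DNA sequence.
#' @param L Maximum word length (1..12).
#' @return An object of class `mr_counts` with elements `L`, `l`
#'   (sequence length) and `counts` (list of named count vectors, one
#'   per word length).
#' @export
build_index <- function(seq, L) {
  seq <- .normalize_seq(seq)
  codes <- .encode_dna(seq)
  l <- length(codes)
  if (!.is_count(L) || L < 1L) stop("`L` must be a positive integer",
                                    call. = FALSE)
  if (L > l) stop("`L` exceeds the sequence length", call. = FALSE)
  if (L > 12L) stop("`L` is limited to 12", call. = FALSE)
  roll <- .rolling_indices(codes, L)
  counts <- vector("list", L)
  for (k in seq_len(L)) {
    idx <- roll[[k]]
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tab <- table(idx)
      v <- as.integer(tab)
      kidx <- as.numeric(names(tab))
      words <- character(length(kidx))
      tmp <- rep("", length(kidx))
      for (j in seq_len(k)) {
        tmp <- paste0(tmp, DNA_BASES[(kidx %/% 4^(k - j)) %% 4 + 1])
      }
      names(v) <- tmp
      counts[[k]] <- v
    } else {
      counts[[k]] <- stats::setNames(integer(0), character(0))
    }
  }
  structure(list(L = as.integer(L), l = l, counts = counts),
            class = "mr_counts")
}

#' @export
print.mr_counts <- function(x, ...) {
  cat("mr_counts: words up to length", x$L, "of a sequence of length",
      x$l, "\n")
  for (k in seq_len(x$L)) {
    cat(sprintf("  k=%d: %d distinct words, %d windows\n",
                k, length(x$counts[[k]]), sum(x$counts[[k]])))
  }
  invisible(x)
}

# single-word lookup against an index (0 if absent)
.index_count <- function(index, w) {
  k <- nchar(w)
  v <- index$counts[[k]][w]
  if (is.na(v)) 0L else as.integer(v)
}

#' Counts of all suffixes of a word
#'
#' Returns the vector `(c_{w,1}, ..., c_{w,|w|})` where `c_{w,k}` is
#' the occurrence count of the length-k suffix of `w` — the count
#' vector entering the simple entropy.
#'
#' @param index An `mr_counts` index from [build_index()].
#' @param w Word of length at most `index$L`.
#' @return Integer vector of length `nchar(w)`.
#' @export
suffix_counts <- function(index, w) {
  stopifnot(inherits(index, "mr_counts"))
  w <- toupper(w)
  k <- nchar(w)
  if (k < 1L) stop("word must be non-empty", call. = FALSE)
  if (k > index$L)
    stop("word longer than the index resolution L = ", index$L, call. = FALSE)
  vapply(seq_len(k), function(j) .index_count(index, substr(w, k - j + 1L, k)),
         integer(1L))
}

#' Watson-Crick reverse complement of a word
#'
#' @param w Word over `{A,C,G,T}` (unambiguous; N is rejected).
#' @return The reverse complement.
#' @export
reverse_complement <- function(w) {
  w <- toupper(w)
  if (grepl("[^ACGT]", w))
    stop("reverse_complement requires an unambiguous word over {A,C,G,T}",
         call. = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
}
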