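# Internal helpers: DNA encoding and word/index arithmetic.
#
# Words of length k over {A,C,G,T} are identified with integers in
# 0..4^k-1, first letter most significant (A=0, C=1, G=2, T=3).  All
# count tables and probability tables are indexed this way, which lets
# suffix extraction (idx %% 4^k), prefix extraction (idx %/% 4^d) and
# overlap tests reduce to integer arithmetic, vectorised over the whole
# word universe.

DNA_BASES <- c("A", "C", "G", "T")

.code_map <- local({
  m <- rep(NA_integer_, 127)
  m[utf8ToInt("A")] <- 0L
  m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L
  m[utf8ToInt("T")] <- 3L
  m
})

# character scalar -> integer codes 0..3, NA for N
.encode_dna <- function(seq) {
  ints <- utf8ToInt(seq)
  bad <- !(ints %in% c(utf8ToInt("A"), utf8ToInt("C"), utf8ToInt("G"),
                       utf8ToInt("T"), utf8ToInt("N")))
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(intToUtf8(ints[bad], multiple = TRUE)), collapse = ", "),
         call. = FALSE)
  }
  .code_map[ints]
}

.decode_dna <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- DNA_BASES[codes[ok] + 1L]
  paste(out, collapse = "")
}

# normalise a sequence string: uppercase + alphabet check
.normalize_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single character string", call. = FALSE)
  seq <- toupper(seq)
  invisible(.encode_dna(seq))  # alphabet validation
  seq
}

.word_to_index <- function(w) {
  codes <- .encode_dna(toupper(w))
  if (length(codes) == 0L)
    stop("word must be non-empty", call. = FALSE)
  if (anyNA(codes))
    stop("word must be over {A,C,G,T} (no N)", call. = FALSE)
  sum(codes * 4^(rev(seq_along(codes)) - 1))
}

# vectorised inverse of .word_to_index for all words of length k
.all_words <- function(k) {
  idx <- 0:(4^k - 1)
  out <- rep("", 4^k)
  for (j in seq_len(k)) {
    out <- paste0(out, DNA_BASES[(idx %/% 4^(k - j)) %% 4 + 1])
  }
  out
}

# reverse-complement permutation on 0-based word indices of length k
.rc_index <- function(idx, k) {
  rc <- 0
  for (j in seq_len(k)) {
    digit <- (idx %/% 4^(k - j)) %% 4
    rc <- rc + (3 - digit) * 4^(j - 1)
  }
  rc
}

# rolling k-mer indices: element i is the index of the window starting
# at i (NA if the window touches an N); list over k = 1..L
.rolling_indices <- function(codes, L) {
  n <- length(codes)
  out <- vector("list", L)
  idx <- as.numeric(codes)
  out[[1L]] <- idx
  if (L >= 2L) {
    for (k in 2:L) {
      idx <- idx[seq_len(n - k + 1L)] * 4 + codes[k:n]
      out[[k]] <- idx
    }
  }
  out
}

# full-universe count vectors (length 4^k) for k = 1..L
.count_vectors <- function(codes, L) {
  roll <- .rolling_indices(codes, L)
  lapply(seq_len(L), function(k) tabulate(roll[[k]] + 1, nbins = 4^k))
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed derivation (keeps results < 2^31)
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
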