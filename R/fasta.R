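#' Read DNA sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]. Sequences are
#' uppercased and validated against the alphabet `{A,C,G,T,N}`; record
#' ids are the first whitespace-delimited token of each description
#' line and must be unique.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    stop("FASTA file contains no records: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    # Biostrings accepts IUPAC ambiguity codes; we only admit N
    seqs[[i]] <- .normalize_seq(seqs[[i]])
  }
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("`seqs` must be a named character vector", call. = FALSE)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
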