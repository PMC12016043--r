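DNA_BASES <- c("A", "C", "G", "T")

#' Generate random DNA sequences
#'
#' @param n Number of sequences.
#' @param length Sequence length in nucleotides.
#' @return Character vector of `n` sequences over A/C/G/T.
#' @keywords internal
random_dna <- function(n, length) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * length, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; `N` is preserved.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between equal-length strings
#'
#' @param a,b Character scalars (or vectors recycled to common length) of
#'   equal string length.
#' @return Integer vector of positionwise mismatch counts.
#' @export
hamming <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

#' Count G+C bases in DNA strings
#' @param x Character vector of DNA sequences.
#' @return Integer vector of G+C counts.
#' @export
gc_count <- function(x) {
  vapply(x, function(s) sum(strsplit(s, "")[[1]] %in% c("G", "C")), integer(1),
         USE.NAMES = FALSE)
}

# Mismatch counts of a fixed pattern against a fixed-offset window of many
# reads; vectorised over reads, loops only over pattern positions.
window_mismatches <- function(reads, pattern, offset) {
  k <- nchar(pattern)
  mm <- integer(length(reads))
  pat <- strsplit(pattern, "")[[1]]
  for (i in seq_len(k)) {
    mm <- mm + (substr(reads, offset + i - 1L, offset + i - 1L) != pat[i])
  }
  mm
}

# Derive a stage seed from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
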