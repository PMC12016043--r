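#' GC-stratified random negative-control enhancers
#'
#' Generates random-sequence negative controls at fixed GC levels: within a
#' level every sequence carries exactly `round(gc_level * length)` G or C
#' bases, placed uniformly at random. These sequences define the null
#' (no-activity) population that activity scores are standardised against.
#'
#' @param count_per_level Number of sequences per GC level.
#' @param gc_levels Numeric vector of GC fractions, each strictly in (0, 1).
#' @param length Sequence length in nucleotides (default 120).
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @return A tibble of enhancer candidates with columns `enhancer_id`,
#'   `sequence`, `category` (`"random_negative"`), `target_tissue` (`"none"`),
#'   `variant_of` (`NA`), `variant_kind` (`"baseline"`), `gc_level`.
#' @export
#' @examples
#' neg <- generate_negative_controls(10, c(0.3, 0.5, 0.7), 120, seed = 7)
#' nrow(neg)  # 30
generate_negative_controls <- function(count_per_level, gc_levels,
                                       length = 120, seed = 1) {
  stopifnot(count_per_level >= 0, length > 0)
  if (any(gc_levels <= 0 | gc_levels >= 1)) {
    stop("gc_levels must be fractions strictly between 0 and 1", call. = FALSE)
  }
  if (count_per_level == 0 || length(gc_levels) == 0) {
    return(tibble::tibble(
      enhancer_id = character(0), sequence = character(0),
      category = character(0), target_tissue = character(0),
      variant_of = character(0), variant_kind = character(0),
      gc_level = numeric(0)
    ))
  }
  set.seed(seed)
  rows <- purrr::map(seq_along(gc_levels), function(i) {
    gc <- gc_levels[i]
    n_gc <- round(gc * length)
    seqs <- vapply(seq_len(count_per_level), function(j) {
      pos_gc <- sample.int(length, n_gc)
      bases <- sample(c("A", "T"), length, replace = TRUE)
      bases[pos_gc] <- sample(c("G", "C"), n_gc, replace = TRUE)
      paste0(bases, collapse = "")
    }, character(1))
    tibble::tibble(
      enhancer_id = sprintf("negGC%02d_%02d", round(gc * 100),
                            seq_len(count_per_level)),
      sequence = seqs,
      category = "random_negative",
      target_tissue = "none",
      variant_of = NA_character_,
      variant_kind = "baseline",
      gc_level = gc
    )
  })
  dplyr::bind_rows(rows)
}

#' Shuffle a motif interval within a sequence
#'
#' Permutes the bases of a window (a transcription-factor binding motif,
#' optionally widened by flanking bases on each side) in place, leaving all
#' other positions untouched. Used to construct motif-disrupted enhancer
#' variants: the shuffled window keeps its base composition, so disruption is
#' attributable to motif grammar, not GC content. If the permutation
#' reproduces the input and the window is not monomorphic, it is re-drawn
#' (at most 10 attempts) so the variant is genuinely disrupted.
#'
#' Coordinates are 1-based and inclusive: the motif occupies
#' `sequence[start..end]` and the shuffled window is
#' `[start - flank, end + flank]`.
#'
#' @param sequence DNA string.
#' @param start,end 1-based inclusive motif coordinates.
#' @param flank Extra bases shuffled on each side of the motif (default 5).
#' @param seed Integer seed.
#' @return The sequence with the window permuted.
#' @export
#' @examples
#' shuffle_interval("AAACGTGCAAA", 4, 8, flank = 0, seed = 1)
shuffle_interval <- function(sequence, start, end, flank = 5, seed = 1) {
  n <- nchar(sequence)
  lo <- start - flank
  hi <- end + flank
  if (lo < 1 || hi > n || start > end) {
    stop("shuffle interval [", lo, ", ", hi, "] outside sequence of length ",
         n, call. = FALSE)
  }
  bases <- strsplit(sequence, "")[[1]]
  window <- bases[lo:hi]
  if (length(unique(window)) == 1L) return(sequence)
  set.seed(seed)
  for (attempt in 1:10) {
    perm <- sample(window)
    if (!identical(perm, window)) break
  }
  bases[lo:hi] <- perm
  paste0(bases, collapse = "")
}

#' Construct a reference/alternative allele pair
#'
#' Returns the matched pair of enhancer sequences for a SNP: the reference
#' sequence unchanged and an alternative sequence differing at exactly the
#' SNP position.
#'
#' @param sequence DNA string carrying the reference allele.
#' @param position 1-based position of the SNP within the sequence.
#' @param ref_base Expected reference base at `position`; mismatch is an error.
#' @param alt_base Alternative base.
#' @return Named list with elements `ref` and `alt`.
#' @export
#' @examples
#' make_allele_pair("AACAA", 3, "C", "G")
make_allele_pair <- function(sequence, position, ref_base, alt_base) {
  observed <- substr(sequence, position, position)
  if (observed != ref_base) {
    stop("reference allele mismatch: sequence has '", observed,
         "' at position ", position, ", expected '", ref_base, "'",
         call. = FALSE)
  }
  alt <- sequence
  substr(alt, position, position) <- alt_base
  list(ref = sequence, alt = alt)
}

#' Pad a sequence with Ns for open-chromatin model prediction
#'
#' Centers the enhancer in a longer window by adding Ns on both sides, the
#' input format expected by convolutional open-chromatin predictors (a 120-nt
#' enhancer padded to 500 nt receives 190 Ns per side). When the padding is
#' odd the extra N goes on the left (5') side. The reverse complement of the
#' padded sequence is returned alongside, since predictors score both strands.
#'
#' @param sequence Character vector of DNA sequences.
#' @param target_length Total padded length; must be >= every input length.
#' @return Tibble with columns `sequence`, `padded`, `padded_rc`.
#' @export
#' @examples
#' pad_for_prediction(strrep("A", 120), 500)
pad_for_prediction <- function(sequence, target_length) {
  n <- nchar(sequence)
  if (any(target_length < n)) {
    stop("target_length shorter than input sequence", call. = FALSE)
  }
  extra <- target_length - n
  left <- ceiling(extra / 2)
  right <- extra - left
  padded <- paste0(strrep("N", left), sequence, strrep("N", right))
  tibble::tibble(
    sequence = sequence,
    padded = padded,
    padded_rc = revcomp(padded)
  )
}
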